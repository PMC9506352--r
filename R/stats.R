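#' Per-group replicate summary
#'
#' @param values Numeric replicate values (one signature metric).
#' @param groups Group labels, same length; order of first appearance is
#'   preserved.
#' @return A `group_table`: data.frame with `group`, `n`, `mean`, `se` plus a
#'   `values` attribute (named list of replicate vectors).
#' @export
group_table <- function(values, groups) {
  stopifnot(length(values) == length(groups), is.numeric(values))
  groups <- as.character(groups)
  levels <- unique(groups)
  split_vals <- lapply(levels, function(g) values[groups == g])
  names(split_vals) <- levels
  n <- vapply(split_vals, length, integer(1L))
  if (any(n < 2L)) {
    stop("every group needs at least 2 replicates for testing", call. = FALSE)
  }
  out <- data.frame(
    group = levels,
    n = n,
    mean = vapply(split_vals, mean, numeric(1L)),
    se = vapply(split_vals, function(v) stats::sd(v) / sqrt(length(v)),
                numeric(1L)),
    row.names = NULL, stringsAsFactors = FALSE
  )
  attr(out, "values") <- split_vals
  class(out) <- c("group_table", "data.frame")
  out
}

#' Pairwise Student t tests between all groups
#'
#' Two-sample t statistic with pooled variance (classical Student test, as
#' used throughout the assay's figure statistics), two-sided p-value, for
#' every unordered pair of groups. No multiple-testing correction is applied
#' by default, matching the plain per-pair tests; Holm correction and the
#' Welch statistic are available behind flags.
#'
#' @param table A [group_table()].
#' @param welch Use the Welch (unpooled) statistic instead of Student's.
#' @param p_adjust Multiplicity correction passed to [stats::p.adjust()]
#'   (`"none"` by default).
#' @return Symmetric p-value matrix with unit diagonal; attribute
#'   `degenerate` marks pairs with zero pooled variance (p set to 1 for equal
#'   means, 0 otherwise).
#' @export
pairwise_tests <- function(table, welch = FALSE, p_adjust = "none") {
  stopifnot(inherits(table, "group_table"))
  vals <- attr(table, "values")
  g <- table$group
  m <- length(g)
  p <- matrix(1, m, m, dimnames = list(g, g))
  degen <- matrix(FALSE, m, m, dimnames = list(g, g))
  pairs <- utils::combn(m, 2L)
  pvec <- numeric(ncol(pairs))
  for (j in seq_len(ncol(pairs))) {
    a <- vals[[pairs[1L, j]]]
    b <- vals[[pairs[2L, j]]]
    pooled_var <- (sum((a - mean(a))^2) + sum((b - mean(b))^2)) /
      (length(a) + length(b) - 2L)
    if (pooled_var <= 0 && stats::var(a) == 0 && stats::var(b) == 0) {
      pvec[j] <- if (isTRUE(all.equal(mean(a), mean(b)))) 1 else 0
      degen[pairs[1L, j], pairs[2L, j]] <- TRUE
      degen[pairs[2L, j], pairs[1L, j]] <- TRUE
    } else {
      pvec[j] <- stats::t.test(a, b, var.equal = !welch)$p.value
    }
  }
  pvec <- stats::p.adjust(pvec, method = p_adjust)
  for (j in seq_len(ncol(pairs))) {
    p[pairs[1L, j], pairs[2L, j]] <- pvec[j]
    p[pairs[2L, j], pairs[1L, j]] <- pvec[j]
  }
  attr(p, "degenerate") <- degen
  p
}

#' Compact letter display from a p-value matrix
#'
#' Insert-and-absorb algorithm on the significance graph: start from one
#' letter covering all groups; for every significant pair occurring in a
#' shared letter column, split that column into two (one without each group
#' of the pair); absorb columns whose group set is contained in another.
#' The result satisfies the display contract exactly: two groups share a
#' letter if and only if their pairwise test is non-significant at `alpha`.
#' Letters are assigned a, b, c, ... in group (column) order.
#'
#' @param p_matrix Symmetric p-value matrix with group names (from
#'   [pairwise_tests()]).
#' @param alpha Significance level (default 0.05).
#' @return A `letter_display`: list with `letters` (named character vector,
#'   e.g. `c(ctrl = "a", low = "ab", high = "b")`) and `alpha`.
#' @export
letter_display <- function(p_matrix, alpha = 0.05) {
  stopifnot(is.matrix(p_matrix), nrow(p_matrix) == ncol(p_matrix))
  g <- rownames(p_matrix)
  if (is.null(g)) g <- as.character(seq_len(nrow(p_matrix)))
  m <- length(g)
  sig <- p_matrix < alpha
  # columns = letters; each a logical membership vector over groups
  cols <- list(rep(TRUE, m))
  pairs <- which(upper.tri(sig) & sig, arr.ind = TRUE)
  if (nrow(pairs)) {
    for (r in seq_len(nrow(pairs))) {
      i <- pairs[r, 1L]; j <- pairs[r, 2L]
      new_cols <- list()
      for (col in cols) {
        if (col[i] && col[j]) {
          c1 <- col; c1[i] <- FALSE
          c2 <- col; c2[j] <- FALSE
          new_cols <- c(new_cols, list(c1, c2))
        } else {
          new_cols <- c(new_cols, list(col))
        }
      }
      # absorb: drop any column whose set is a subset of another
      keep <- rep(TRUE, length(new_cols))
      for (a in seq_along(new_cols)) {
        for (b in seq_along(new_cols)) {
          if (a != b && keep[a] &&
              all(new_cols[[a]] <= new_cols[[b]]) &&
              !identical(new_cols[[a]], new_cols[[b]])) {
            keep[a] <- FALSE
          }
        }
      }
      # drop exact duplicates, keeping the first
      new_cols <- new_cols[keep]
      if (length(new_cols) > 1L) {
        dup <- duplicated(vapply(new_cols, paste, character(1L),
                                 collapse = ""))
        new_cols <- new_cols[!dup]
      }
      cols <- new_cols
    }
  }
  # order columns by first member so letters read in group order
  first <- vapply(cols, function(col) which(col)[1L], integer(1L))
  cols <- cols[order(first)]
  letters_out <- vapply(seq_len(m), function(i) {
    paste(letters[which(vapply(cols, `[`, logical(1L), i))], collapse = "")
  }, character(1L))
  names(letters_out) <- g
  structure(list(letters = letters_out, alpha = alpha),
            class = "letter_display")
}

#' @export
print.letter_display <- function(x, ...) {
  cat("<letter_display> alpha =", x$alpha, "\n")
  print(x$letters)
  invisible(x)
}

#' Aggregate signature metrics against transferred energy
#'
#' Joins per-well integrated Ca2+ signals to the per-treatment energy dose
#' and summarises mean, SE and n per treatment, sorted by energy: the
#' dose-response table plotted as integrated signal versus energy per unit
#' mass.
#'
#' @param metrics data.frame with at least `treatment` and `auc` columns
#'   (one row per well).
#' @param doses data.frame with `treatment`, `energy_per_mass` and optionally
#'   `source`, `frequency_khz`, `activation_time_s`.
#' @return A `dose_response` data.frame sorted by `energy_per_mass` with
#'   columns `treatment`, (optional design columns), `energy_per_mass`,
#'   `mean_auc`, `se_auc`, `n`. Treatments without a dose record are dropped
#'   with a warning.
#' @export
build_dose_response <- function(metrics, doses) {
  stopifnot(all(c("treatment", "auc") %in% names(metrics)),
            all(c("treatment", "energy_per_mass") %in% names(doses)))
  missing <- setdiff(unique(metrics$treatment), doses$treatment)
  if (length(missing)) {
    warning("no dose record for treatment(s): ",
            paste(missing, collapse = ", "), "; rows excluded",
            call. = FALSE)
    metrics <- metrics[!metrics$treatment %in% missing, , drop = FALSE]
  }
  agg <- lapply(split(metrics, metrics$treatment), function(d) {
    data.frame(treatment = d$treatment[1L],
               mean_auc = mean(d$auc),
               se_auc = stats::sd(d$auc) / sqrt(nrow(d)),
               n = nrow(d),
               stringsAsFactors = FALSE)
  })
  agg <- do.call(rbind, agg)
  keep <- intersect(c("treatment", "source", "frequency_khz",
                      "activation_time_s", "energy_per_mass"), names(doses))
  out <- merge(agg, doses[, keep, drop = FALSE], by = "treatment")
  out <- out[order(out$energy_per_mass), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("dose_response", "data.frame")
  out
}
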