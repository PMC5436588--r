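# Per-cell NFC change rates, their regression on road-indicator changes
# (explanatory power = adjusted R^2, as percent), and variation partitioning
# of the combined main-vs-secondary road effect.

road_indicator_cols <- function() {
  paste0(rep(c("SRL", "DNR", "NON", "MND"), 2), "_",
         rep(c("main", "secondary"), each = 4))
}

#' Per-cell change records between two periods
#'
#' Change rate is the NFC difference per decade (the interval length in
#' years divided by 10 as denominator); differences of each road indicator
#' are computed identically (as raw differences).
#'
#' @param cell_table per-cell, per-period table with an NFC column (observed
#'   or hindcast).
#' @param t1,t2 period labels, `t1` earlier.
#' @param years named numeric vector: period label -> representative year.
#' @param rate one of `"per_decade"` (default), `"raw"` (plain difference)
#'   or `"relative"` (difference over initial NFC; cells with zero initial
#'   NFC are dropped).
#' @return `data.frame`: `cell`, `nfc_t1`, `nfc_t2`, `d_nfc`, `change_rate`,
#'   and `d_<indicator>` for the eight road indicators present.
#' @export
change_table <- function(cell_table, t1, t2, years, rate = c("per_decade", "raw", "relative")) {
  rate <- match.arg(rate)
  for (p in c(t1, t2)) if (!p %in% cell_table$period) stop("period not in table: ", p)
  a <- cell_table[cell_table$period == t1, , drop = FALSE]
  b <- cell_table[cell_table$period == t2, , drop = FALSE]
  b <- b[match(a$cell, b$cell), , drop = FALSE]
  d_nfc <- b$NFC - a$NFC
  out <- data.frame(cell = a$cell, nfc_t1 = a$NFC, nfc_t2 = b$NFC, d_nfc = d_nfc)
  out$change_rate <- switch(rate,
    per_decade = d_nfc / ((years[[t2]] - years[[t1]]) / 10),
    raw = d_nfc,
    relative = d_nfc / a$NFC)
  for (col in intersect(road_indicator_cols(), names(cell_table))) {
    out[[paste0("d_", col)]] <- b[[col]] - a[[col]]
  }
  if (rate == "relative") out <- out[a$NFC > 0, , drop = FALSE]
  out$period_pair <- paste(t1, t2, sep = ":")
  out
}

#' Simple linear regression summary
#'
#' Ordinary least squares of `y` on `x` with the standard adjusted R^2
#' (reported as percent), F statistic and two-sided p value.
#'
#' @param x predictor vector (not constant).
#' @param y response vector, same length, n >= 3.
#' @return List of class `fs_regression`: `slope`, `intercept`,
#'   `r_squared`, `adj_r_squared` (percent), `f`, `p`, `n`.
#' @export
simple_regression <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 3)
  if (stats::sd(x) == 0) stop("degenerate predictor: x is constant")
  fit <- stats::lm(y ~ x)
  s <- summary(fit)
  structure(list(slope = unname(stats::coef(fit)[2]),
                 intercept = unname(stats::coef(fit)[1]),
                 r_squared = 100 * s$r.squared,
                 adj_r_squared = 100 * s$adj.r.squared,
                 f = unname(s$fstatistic[1]),
                 p = unname(stats::pf(s$fstatistic[1], s$fstatistic[2],
                                      s$fstatistic[3], lower.tail = FALSE)),
                 n = length(x)),
            class = "fs_regression")
}

#' @export
print.fs_regression <- function(x, ...) {
  cat(sprintf("slope %.4g, adj R2 %.2f%%, F %.3g, p %.3g, n %d\n",
              x$slope, x$adj_r_squared, x$f, x$p, x$n))
  invisible(x)
}

#' Explanatory power of each road-indicator change
#'
#' One simple linear regression of the NFC change rate on the change of
#' each road indicator, per class; the adjusted R^2 (percent) is the
#' indicator's explanatory power.
#'
#' @param changes a change table from [change_table()] (one period pair) or
#'   several row-bound pairs.
#' @return `data.frame`: `period_pair`, `class`, `indicator`,
#'   `adj_r_squared`, `p`, `slope`, `n`; indicators whose change is constant
#'   or all-missing are skipped with a message.
#' @export
indicator_power <- function(changes) {
  out <- list()
  for (pp in unique(changes$period_pair)) {
    ch <- changes[changes$period_pair == pp, , drop = FALSE]
    for (col in intersect(paste0("d_", road_indicator_cols()), names(ch))) {
      x <- ch[[col]]
      keep <- !is.na(x) & !is.na(ch$change_rate)
      if (sum(keep) < 3 || stats::sd(x[keep]) == 0) {
        message("skipping degenerate indicator ", col, " for ", pp)
        next
      }
      r <- simple_regression(x[keep], ch$change_rate[keep])
      ind <- sub("^d_", "", col)
      out[[length(out) + 1]] <- data.frame(
        period_pair = pp,
        class = sub("^.*_", "", ind),
        indicator = sub("_.*$", "", ind),
        adj_r_squared = r$adj_r_squared, p = r$p, slope = r$slope, n = r$n)
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

# Adjusted R^2 (percent) of a multiple regression of the change rate on a
# set of delta columns, dropping collinear columns with a warning.
adj_r2_multi <- function(changes, cols) {
  keep <- stats::complete.cases(changes[c("change_rate", cols)])
  df <- changes[keep, , drop = FALSE]
  nz <- cols[vapply(df[cols], function(v) stats::sd(v) > 0, logical(1))]
  # every predictor constant: intercept-only model, adjusted R^2 = 0
  if (!length(nz)) return(0)
  fit <- stats::lm(stats::reformulate(nz, "change_rate"), data = df)
  if (any(is.na(stats::coef(fit)))) {
    drop <- names(stats::coef(fit))[is.na(stats::coef(fit))]
    warning("collinear columns dropped: ", paste(drop, collapse = ", "))
  }
  100 * summary(fit)$adj.r.squared
}

#' Variation partition of main vs secondary road effects
#'
#' Three multiple regressions of the NFC change rate — on the four main-road
#' indicator changes, on the four secondary-road indicator changes, and on
#' all eight — decomposed by the standard adjusted-R^2 partition algebra:
#' unique(main) = combined - secondary, unique(secondary) = combined - main,
#' shared = main + secondary - combined. The three components sum to the
#' combined adjusted R^2 by identity.
#'
#' @param changes a change table for one period pair.
#' @return List of class `fs_partition` with `adj_r2_main`,
#'   `adj_r2_secondary`, `adj_r2_combined`, `unique_main`,
#'   `unique_secondary`, `shared` (all percent).
#' @export
variation_partition <- function(changes) {
  main_cols <- paste0("d_", c("SRL", "DNR", "NON", "MND"), "_main")
  sec_cols <- paste0("d_", c("SRL", "DNR", "NON", "MND"), "_secondary")
  stopifnot(all(c(main_cols, sec_cols) %in% names(changes)))
  m <- adj_r2_multi(changes, main_cols)
  s <- adj_r2_multi(changes, sec_cols)
  c2 <- adj_r2_multi(changes, c(main_cols, sec_cols))
  structure(list(adj_r2_main = m, adj_r2_secondary = s, adj_r2_combined = c2,
                 unique_main = c2 - s, unique_secondary = c2 - m,
                 shared = m + s - c2),
            class = "fs_partition")
}

#' @export
print.fs_partition <- function(x, ...) {
  cat(sprintf(paste0("adj R2 (%%): main %.2f, secondary %.2f, combined %.2f\n",
                     "unique main %.2f, unique secondary %.2f, shared %.2f\n"),
              x$adj_r2_main, x$adj_r2_secondary, x$adj_r2_combined,
              x$unique_main, x$unique_secondary, x$shared))
  invisible(x)
}

#' Regression of the NFC change rate on initial NFC
#'
#' The site-specific NFC-vs-change-rate relationship: a positive slope means
#' cells that start with low NFC lose forest fastest.
#'
#' @param cell_table per-cell, per-period table with NFC.
#' @param t1,t2 period labels.
#' @param years named period -> year vector.
#' @return An `fs_regression` (see [simple_regression()]).
#' @export
nfc_vs_rate_slope <- function(cell_table, t1, t2, years) {
  ch <- change_table(cell_table, t1, t2, years)
  simple_regression(ch$nfc_t1, ch$change_rate)
}
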