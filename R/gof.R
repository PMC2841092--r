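## Binned chi-square comparison of fitted families, 10 g/day bandwidth.
## The chi-square values are descriptive fit statistics, not hypothesis
## tests: no p-values are attached.

#' Bin drinker volumes with a fixed bandwidth
#'
#' Bins are half-open `[lower, upper)` up to `top_edge`, plus an open top bin
#' `[top_edge, Inf)`; a value exactly at `top_edge` falls in the top bin.
#'
#' @param x positive volumes in grams/day.
#' @param bandwidth bin width in grams/day (default 10).
#' @param top_edge lower edge of the open top bin (default 100).
#' @return Integer vector of counts, one per bin, with attributes
#'   `edges` (finite lower edges plus `Inf`) and `labels`.
#' @examples
#' bin_volumes(c(5, 15, 250))
#' @export
bin_volumes <- function(x, bandwidth = 10, top_edge = 100) {
  x <- as.numeric(x)
  if (length(x) == 0) stop("no volumes to bin", call. = FALSE)
  if (any(!is.finite(x)) || any(x <= 0)) {
    stop("volumes must be positive and finite", call. = FALSE)
  }
  stopifnot(bandwidth > 0, top_edge > bandwidth)
  lower <- seq(0, top_edge, by = bandwidth)
  edges <- c(lower, Inf)
  idx <- findInterval(x, edges)                 # [edge_i, edge_{i+1})
  counts <- tabulate(idx, nbins = length(edges) - 1)
  labels <- c(paste(lower[-length(lower)], lower[-1], sep = " - "),
              paste0(top_edge, " +"))
  structure(as.integer(counts), edges = edges, labels = labels)
}

#' Expected bin fractions under a fitted model
#'
#' @param dist a `"drinkdist"` or `"drinkfit"`.
#' @param edges increasing vector of bin edges starting at 0 and ending at
#'   `Inf` (as produced by [bin_volumes()]).
#' @return Numeric vector of expected probability per bin; sums to 1.
#' @export
expected_bin_fractions <- function(dist, edges) {
  stopifnot(inherits(dist, "drinkdist"))
  edges <- as.numeric(edges)
  if (is.unsorted(edges, strictly = TRUE) || edges[1] != 0 ||
      !is.infinite(edges[length(edges)])) {
    stop("edges must be strictly increasing from 0 to Inf", call. = FALSE)
  }
  cdf <- c(0, .fam_p(dist, edges[c(-1, -length(edges))]), 1)
  diff(cdf)
}

#' Chi-square cells for observed counts against expected fractions
#'
#' Computes `(obs_i - n * frac_i)^2 / (n * frac_i)` per bin, the total over
#' all bins, and the sub-total excluding the open top bin (fit "up to 100 g
#' pure alcohol per day" when the default binning is used).
#'
#' @param observed integer counts per bin.
#' @param expected_frac expected probability per bin (sums to 1).
#' @param warn_small warn when any expected count is below 5.
#' @return List with `cells`, `total`, `sub_top` (total excluding the last
#'   bin) and `n`.
#' @export
chi_square_stat <- function(observed, expected_frac, warn_small = FALSE) {
  observed <- as.numeric(observed)
  n <- sum(observed)
  if (n <= 0) stop("no observations", call. = FALSE)
  if (length(observed) != length(expected_frac)) {
    stop("observed and expected lengths differ", call. = FALSE)
  }
  if (abs(sum(expected_frac) - 1) > 1e-8) {
    stop("expected fractions must sum to 1", call. = FALSE)
  }
  exp_counts <- n * expected_frac
  zero <- exp_counts <= 0 & observed > 0
  if (any(zero)) {
    stop("expected count is zero in occupied bin(s) ",
         paste(which(zero), collapse = ", "), call. = FALSE)
  }
  cells <- ifelse(exp_counts > 0, (observed - exp_counts)^2 / exp_counts, 0)
  if (warn_small && any(exp_counts < 5)) {
    warning(sum(exp_counts < 5), " bin(s) with expected count < 5",
            call. = FALSE)
  }
  list(cells = cells, total = sum(cells),
       sub_top = sum(cells[-length(cells)]), n = n)
}

#' Goodness-of-fit table for several fitted families
#'
#' Reproduces the layout of a per-stratum fit table: one row per 10 g/day
#' bin with the observed count, the empirical percentage, each family's
#' fitted percentage and each family's chi-square cell; plus per-family
#' totals and sub-100 totals.
#'
#' @param x positive drinker volumes (grams/day).
#' @param fits named list of `"drinkfit"`/`"drinkdist"` objects (names are
#'   family labels; defaults to each fit's family).
#' @param bandwidth,top_edge binning parameters, see [bin_volumes()].
#' @return An object of class `"gof_comparison"`: list with `table`
#'   (data.frame), `totals`, `sub_top_totals` (named per family), `n`.
#' @examples
#' set.seed(42)
#' x <- rgamma(3000, 0.45, scale = 45)
#' fits <- lapply(c(gamma = "gamma", lognormal = "lognormal",
#'                  weibull = "weibull"), fit_consumption, x = x)
#' gof_table(x, fits)
#' @export
gof_table <- function(x, fits, bandwidth = 10, top_edge = 100) {
  if (!length(fits)) stop("no fitted models supplied", call. = FALSE)
  if (is.null(names(fits)) || any(!nzchar(names(fits)))) {
    names(fits) <- vapply(fits, function(f) f$family, character(1))
  }
  obs <- bin_volumes(x, bandwidth, top_edge)
  edges <- attr(obs, "edges")
  n <- sum(obs)
  tab <- data.frame(bin = attr(obs, "labels"), count = as.integer(obs),
                    empirical_pct = 100 * obs / n,
                    check.names = FALSE, stringsAsFactors = FALSE)
  totals <- sub_tot <- setNames(numeric(length(fits)), names(fits))
  for (nm in names(fits)) {
    frac <- expected_bin_fractions(fits[[nm]], edges)
    cs <- chi_square_stat(obs, frac)
    tab[[paste0(nm, "_pct")]] <- 100 * frac
    tab[[paste0(nm, "_chisq")]] <- cs$cells
    totals[nm] <- cs$total
    sub_tot[nm] <- cs$sub_top
  }
  structure(list(table = tab, totals = totals, sub_top_totals = sub_tot,
                 n = n, bandwidth = bandwidth, top_edge = top_edge),
            class = "gof_comparison")
}

#' @export
print.gof_comparison <- function(x, digits = 1, ...) {
  cat(sprintf("Binned goodness of fit, n = %d, bandwidth %g g/day\n",
              x$n, x$bandwidth))
  tab <- x$table
  num <- vapply(tab, is.numeric, logical(1))
  tab[num] <- lapply(tab[num], round, digits = digits)
  print(tab, row.names = FALSE)
  cat("chi-square totals:            ",
      paste(names(x$totals), round(x$totals, digits), sep = " = ",
            collapse = ", "), "\n")
  cat(sprintf("chi-square up to %g g/day:  %s\n", x$top_edge,
      paste(names(x$sub_top_totals), round(x$sub_top_totals, digits),
            sep = " = ", collapse = ", ")))
  cat("best fit:", rank_families(x$totals)[1], "\n")
  invisible(x)
}

#' Rank families by chi-square total
#'
#' @param totals a named numeric vector of chi-square totals, or a
#'   `"gof_comparison"` object (its overall totals are used).
#' @param sub_top rank by the sub-top-bin totals instead (for
#'   `"gof_comparison"` input).
#' @return Character vector of family names, best (smallest total) first;
#'   ties broken alphabetically.
#' @export
rank_families <- function(totals, sub_top = FALSE) {
  if (inherits(totals, "gof_comparison")) {
    totals <- if (sub_top) totals$sub_top_totals else totals$totals
  }
  if (is.null(names(totals))) stop("totals must be named", call. = FALSE)
  names(totals)[order(totals, names(totals))]
}
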