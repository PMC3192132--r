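## Rarefaction of eliminated sites: how many RDD sites are explained as
## individuals' genomic data are added in random order, plus saturation
## extrapolation to cohort sizes beyond the one sampled.

#' Build a rarefaction curve of eliminated sites
#'
#' For each random ordering of individuals, `eliminated(k)` is the size of
#' the union of the baseline set (sites explained by the reference genome
#' alone) with the elimination sets of the first `k` individuals. The curve
#' is the per-`k` mean (and sd) across orderings.
#'
#' @param elimination_sets named list: individual -> character vector of
#'   site ids eliminated by that individual's genomic data.
#' @param baseline character vector of site ids eliminated by the reference
#'   genome alone (value of the curve at k = 0).
#' @param replicates number of random orderings (published curve: 1,000).
#' @param seed integer seed.
#' @param method `"sample"` draws `replicates` random orderings;
#'   `"exhaustive"` enumerates all n! orderings (n <= 8) and returns the
#'   exact expectation.
#' @return object of class `RarefactionCurve`: list with `k` (0..n),
#'   `mean_eliminated`, `sd_eliminated`, `baseline` (count), `replicates`,
#'   `seed`, `n_individuals`, and `per_replicate` (matrix, replicates x
#'   (n+1)).
#' @export
build_curve <- function(elimination_sets, baseline, replicates = 1000L,
                        seed = NULL, method = c("sample", "exhaustive")) {
  method <- match.arg(method)
  n <- length(elimination_sets)
  inds <- names(elimination_sets) %||% as.character(seq_len(n))
  baseline <- unique(baseline)
  nb <- length(baseline)
  if (n == 0) {
    res <- list(k = 0L, mean_eliminated = nb, sd_eliminated = 0,
                baseline = nb, replicates = 0L, seed = seed,
                n_individuals = 0L,
                per_replicate = matrix(nb, 1, 1))
    class(res) <- "RarefactionCurve"
    return(res)
  }
  # only sites not already in the baseline can change the curve
  extra <- lapply(elimination_sets, function(s) setdiff(unique(s), baseline))
  sites <- unique(unlist(extra))
  M <- vapply(extra, function(s) sites %in% s, logical(length(sites)))
  M <- matrix(M, nrow = length(sites), ncol = n)

  perms <- if (method == "exhaustive") {
    if (n > 8) stop("exhaustive enumeration limited to n <= 8", call. = FALSE)
    all_permutations(n)
  } else {
    with_seed(seed, replicate(replicates, sample.int(n), simplify = FALSE))
  }
  curve_one <- function(perm) {
    if (!nrow(M)) return(rep(nb, n + 1L))
    Mp <- M[, perm, drop = FALSE]
    first <- apply(Mp, 1L, function(r) which(r)[1])
    first <- first[!is.na(first)]
    nb + c(0L, cumsum(tabulate(first, nbins = n)))
  }
  per_rep <- do.call(rbind, lapply(perms, curve_one))
  res <- list(k = 0:n,
              mean_eliminated = colMeans(per_rep),
              sd_eliminated = apply(per_rep, 2, sd),
              baseline = nb, replicates = length(perms), seed = seed,
              n_individuals = n, per_replicate = per_rep)
  class(res) <- "RarefactionCurve"
  res
}

all_permutations <- function(n) {
  if (n == 1) return(list(1L))
  out <- list()
  for (i in seq_len(n)) {
    rest <- all_permutations(n - 1L)
    out <- c(out, lapply(rest, function(p) c(i, setdiff(seq_len(n), i)[p])))
  }
  out
}

#' @export
print.RarefactionCurve <- function(x, ...) {
  cat("RarefactionCurve:", x$n_individuals, "individuals,",
      x$replicates, "orderings; baseline", x$baseline, "->",
      format(x$mean_eliminated[length(x$mean_eliminated)], digits = 6),
      "at k =", x$n_individuals, "\n")
  invisible(x)
}

#' Fit a saturation model to a rarefaction curve
#'
#' Least-squares fit of `mean_eliminated(k) = baseline + E_max * k /
#' (K_half + k)` over k >= 1 with the baseline held fixed
#' (Michaelis-Menten form, invertible in closed form). An exponential
#' alternative `baseline + E_max * (1 - exp(-k / tau))` is available; the
#' extrapolation method behind the published curve is not stated, so both
#' forms are provided and reports name the one used.
#'
#' @param curve a `RarefactionCurve`.
#' @param form `"michaelis"` (default) or `"exponential"`.
#' @return object of class `SaturationFit`: list with `form`, `E_max`,
#'   `K_half` (or `tau`), `baseline`, `residual` (sum of squares) and
#'   `predicted(k)`.
#' @export
fit_saturation <- function(curve, form = c("michaelis", "exponential")) {
  form <- match.arg(form)
  k <- curve$k[curve$k >= 1]
  y <- curve$mean_eliminated[curve$k >= 1] - curve$baseline
  if (length(k) < 3)
    stop("need at least 3 points with k >= 1", call. = FALSE)
  if (max(y) <= 0 || all(abs(diff(y)) < 1e-12) || any(diff(y) < -1e-9))
    stop("curve is flat or non-increasing above baseline; fit rejected",
         call. = FALSE)
  df <- data.frame(k = k, y = y)
  cf <- if (form == "michaelis") {
    # linearization k/y = K/E + k/E is exact on model-generated data and a
    # good start otherwise; nls refines it (guarded: nls balks at
    # zero-residual input)
    lin <- stats::lm(I(k / y) ~ k, data = df[df$y > 0, ])
    e0 <- 1 / coef(lin)[[2]]
    k0 <- coef(lin)[[1]] * e0
    if (!is.finite(e0) || e0 <= 0) { e0 <- max(y) * 1.5; k0 <- max(k) / 2 }
    if (!is.finite(k0) || k0 <= 0) k0 <- max(k) / 2
    start <- c(E_max = e0, K_half = k0)
    refine_nls(y ~ E_max * k / (K_half + k), df, start)
  } else {
    e0 <- max(y) * 1.2
    t0 <- max(1, k[which.min(abs(y - max(y) * 0.632))])
    start <- c(E_max = e0, tau = t0)
    refine_nls(y ~ E_max * (1 - exp(-k / tau)), df, start)
  }
  baseline <- curve$baseline
  predicted <- if (form == "michaelis") {
    function(k) baseline + cf[["E_max"]] * k / (cf[["K_half"]] + k)
  } else {
    function(k) baseline + cf[["E_max"]] * (1 - exp(-k / cf[["tau"]]))
  }
  res <- list(form = form, E_max = cf[["E_max"]],
              K_half = if (form == "michaelis") cf[["K_half"]] else NA_real_,
              tau = if (form == "exponential") cf[["tau"]] else NA_real_,
              baseline = baseline,
              residual = sum((y - (predicted(k) - baseline))^2),
              predicted = predicted)
  class(res) <- "SaturationFit"
  res
}

refine_nls <- function(formula, df, start) {
  fit <- tryCatch(
    suppressWarnings(nls(formula, data = df, start = as.list(start),
                         control = list(maxiter = 500, warnOnly = TRUE))),
    error = function(e) NULL)
  if (is.null(fit)) return(start)
  cf <- coef(fit)
  # keep the refinement only if it does not worsen the fit
  sse <- function(p) {
    env <- c(as.list(df), as.list(p))
    sum((df$y - eval(formula[[3]], env))^2)
  }
  if (sse(cf) <= sse(start) + 1e-12) cf else start
}

#' @export
print.SaturationFit <- function(x, ...) {
  cat("SaturationFit (", x$form, "): E_max = ",
      format(x$E_max, digits = 6),
      if (x$form == "michaelis") paste0(", K_half = ",
                                        format(x$K_half, digits = 6))
      else paste0(", tau = ", format(x$tau, digits = 6)),
      ", baseline = ", x$baseline, "\n", sep = "")
  invisible(x)
}

#' Individuals needed to eliminate a target fraction of sites
#'
#' Closed-form inversion of the fitted saturation model: the smallest
#' integer `k` with `predicted(k) >= target_fraction * total_sites`.
#'
#' @param fit a `SaturationFit`.
#' @param total_sites total number of candidate sites.
#' @param target_fraction fraction of sites to eliminate (e.g. 0.9).
#' @return list with `reachable` (logical), `k` (integer, `NA` when the
#'   asymptote lies below the target) and `target_sites`.
#' @export
individuals_to_fraction <- function(fit, total_sites, target_fraction) {
  target <- target_fraction * total_sites
  y <- target - fit$baseline
  if (y <= 0)
    return(list(reachable = TRUE, k = 0L, target_sites = target))
  if (y >= fit$E_max)
    return(list(reachable = FALSE, k = NA_integer_, target_sites = target))
  k_real <- if (fit$form == "michaelis") {
    fit$K_half * y / (fit$E_max - y)
  } else {
    -fit$tau * log(1 - y / fit$E_max)
  }
  k <- as.integer(ceiling(k_real - 1e-9))
  list(reachable = TRUE, k = k, target_sites = target)
}
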