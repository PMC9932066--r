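# The model-fitting stage: collinearity screen, Poisson -> negative
# binomial ladder, bounded all-subsets AIC selection, spatial
# autocorrelation diagnostics, and the small meta-statistics on
# delta-transformed metrics.

#' Iterative variance-inflation-factor screen
#'
#' Computes the VIF of each predictor (1 / (1 - R^2) of that predictor
#' regressed on all others) and iteratively drops the worst predictor until
#' all VIFs are at or below the cutoff. Perfectly collinear predictors are
#' dropped first with a warning.
#'
#' @param X data.frame or matrix of numeric candidate predictors.
#' @param cutoff VIF threshold (default 3).
#' @return list with `retained` (names), `dropped` (names in drop order)
#'   and `vif` (final VIFs).
#' @export
vifScreen <- function(X, cutoff = 3) {
  X <- as.data.frame(X)
  if (ncol(X) < 2) stop("need at least 2 predictors")
  vifOne <- function(j, Xc) {
    fit <- lm(Xc[[j]] ~ ., data = Xc[-j])
    r2 <- summary(fit)$r.squared
    if (r2 > 1 - 1e-10) Inf else 1 / (1 - r2)
  }
  dropped <- character(0)
  repeat {
    v <- vapply(seq_along(X), vifOne, numeric(1), Xc = X)
    names(v) <- names(X)
    if (all(is.finite(v)) && max(v) <= cutoff) break
    worst <- which.max(v)
    if (!is.finite(v[worst])) {
      warning("perfect collinearity: dropping '", names(X)[worst], "'")
    }
    dropped <- c(dropped, names(X)[worst])
    X <- X[-worst]
    if (ncol(X) < 2) {
      v <- setNames(1, names(X))
      break
    }
  }
  list(retained = names(X), dropped = dropped, vif = v)
}

.pearsonDispersion <- function(fit) {
  sum(residuals(fit, type = "pearson")^2) / df.residual(fit)
}

#' Fit a count or Gaussian model with the overdispersion ladder
#'
#' Counts are fitted by Poisson maximum likelihood; when the Pearson
#' dispersion statistic (chi-squared / residual df) exceeds
#' `dispersionThreshold` the model is refitted as negative binomial with
#' ML-estimated dispersion. Continuous responses use a Gaussian linear
#' model. Returns the model and its summary statistics; the pseudo-R^2 for
#' GLMs is \eqn{1 - deviance/null\ deviance} (ordinary R^2 for LMs).
#'
#' @param response numeric response (non-negative integers for counts).
#' @param X data.frame of predictors (possibly zero columns for an
#'   intercept-only model).
#' @param family `"auto"` (counts -> poisson ladder, otherwise gaussian),
#'   `"poisson"`, `"nbinom"` or `"gaussian"`.
#' @param dispersionThreshold Pearson dispersion that triggers the negative
#'   binomial refit (default 1.5).
#' @return list of class `"modelResult"`: `family`, `coefficients` (matrix
#'   with estimates, SE, z/t and p), `aic`, `dispersion`, `r2`, `fit`.
#' @export
fitCountModel <- function(response, X = NULL,
                          family = c("auto", "poisson", "nbinom", "gaussian"),
                          dispersionThreshold = 1.5) {
  family <- match.arg(family)
  X <- if (is.null(X) || ncol(as.data.frame(X)) == 0) {
    data.frame(row.names = seq_along(response))
  } else as.data.frame(X)
  if (ncol(X)) {
    constant <- vapply(X, function(p) sd(p) == 0, logical(1))
    if (any(constant)) {
      stop("zero-variance predictor(s): ",
           paste(names(X)[constant], collapse = ", "))
    }
  }
  isCount <- all(response >= 0) && all(response == round(response))
  if (family %in% c("poisson", "nbinom") && !isCount) {
    stop("count families need non-negative integer responses")
  }
  ladder <- family == "auto" && isCount
  if (family == "auto") family <- if (isCount) "poisson" else "gaussian"
  dat <- cbind(data.frame(.y = response), X)
  form <- if (ncol(X)) stats::as.formula(paste(".y ~", paste(names(X), collapse = " + ")))
          else .y ~ 1
  if (family == "gaussian") {
    fit <- lm(form, data = dat)
    sm <- summary(fit)
    return(structure(list(
      family = "gaussian", coefficients = sm$coefficients, aic = AIC(fit),
      dispersion = sm$sigma^2, r2 = sm$r.squared, fit = fit),
      class = "modelResult"))
  }
  fit <- glm(form, data = dat, family = poisson())
  if (!fit$converged) stop("Poisson fit did not converge")
  disp <- .pearsonDispersion(fit)
  usedFamily <- "poisson"
  if (family == "nbinom" || (ladder && disp > dispersionThreshold)) {
    nb <- tryCatch(glm.nb(form, data = dat), error = function(e) NULL,
                   warning = function(w) suppressWarnings(glm.nb(form, data = dat)))
    if (!is.null(nb)) {
      fit <- nb
      usedFamily <- "nbinom"
      disp <- .pearsonDispersion(fit)
    }
  }
  sm <- summary(fit)
  structure(list(
    family = usedFamily, coefficients = sm$coefficients, aic = AIC(fit),
    dispersion = disp, r2 = 1 - fit$deviance / fit$null.deviance, fit = fit),
    class = "modelResult")
}

#' @export
print.modelResult <- function(x, ...) {
  cat(sprintf("modelResult [%s], AIC %.2f, R2 %.3f, dispersion %.2f\n",
              x$family, x$aic, x$r2, x$dispersion))
  stats::printCoefmat(x$coefficients)
  invisible(x)
}

#' Bounded all-subsets AIC model selection
#'
#' Exhaustively fits every predictor subset of size 0..`maxTerms` (the
#' bound guards against overfitting at small n) and returns the
#' minimum-AIC model together with the full ranking table. Candidates
#' should already have passed [vifScreen()].
#'
#' @param response response vector.
#' @param X data.frame of candidate predictors.
#' @param maxTerms maximum number of predictors per model (default 3).
#' @param ... passed to [fitCountModel()].
#' @return list with `best` (a `modelResult`), `bestTerms`, and `ranking`
#'   (data.frame of subsets and AICs, best first).
#' @export
subsetSelectAic <- function(response, X, maxTerms = 3, ...) {
  X <- as.data.frame(X)
  maxTerms <- min(maxTerms, ncol(X))
  subsets <- list(integer(0))
  for (k in seq_len(maxTerms)) {
    subsets <- c(subsets,
                 lapply(asplit(combn(ncol(X), k), 2), as.integer))
  }
  fits <- lapply(subsets, function(idx) {
    tryCatch(fitCountModel(response, X[, idx, drop = FALSE], ...),
             error = function(e) NULL)
  })
  ok <- !vapply(fits, is.null, logical(1))
  if (!any(ok)) stop("no candidate subset could be fitted")
  aics <- vapply(fits[ok], function(f) f$aic, numeric(1))
  terms <- vapply(subsets[ok], function(idx) {
    if (!length(idx)) "(intercept)" else paste(names(X)[idx], collapse = "+")
  }, character(1))
  ord <- order(aics)
  bestIdx <- which(ok)[ord[1]]
  list(best = fits[[bestIdx]],
       bestTerms = if (length(subsets[[bestIdx]]))
         names(X)[subsets[[bestIdx]]] else character(0),
       ranking = data.frame(terms = terms[ord],
                            n_terms = vapply(subsets[ok], length, 1L)[ord],
                            aic = aics[ord], stringsAsFactors = FALSE))
}

#' Moran's I on model residuals
#'
#' Spatial autocorrelation of residuals with row-normalised
#' inverse-distance weights, via the normal-approximation test. When
#' autocorrelation is detected at `alpha`, the result flags that a
#' generalised-least-squares refit with a spatial correlation structure is
#' recommended (the refit itself is outside this package's scope).
#'
#' @param residuals numeric residuals, length n >= 4.
#' @param coords n x 2 site coordinates.
#' @param alpha significance level for the `gls_recommended` flag.
#' @return list: `observed`, `expected` (`-1/(n-1)`), `sd`, `p`,
#'   `gls_recommended`.
#' @export
moransI <- function(residuals, coords, alpha = 0.05) {
  coords <- as.matrix(coords)
  n <- length(residuals)
  if (n < 4) stop("need at least 4 observations")
  d <- as.matrix(dist(coords))
  if (any(d[upper.tri(d)] == 0)) stop("coincident coordinates")
  w <- 1 / d
  diag(w) <- 0
  w <- w / rowSums(w)
  mi <- Moran.I(residuals, weight = w)
  list(observed = mi$observed, expected = mi$expected, sd = mi$sd,
       p = mi$p.value, gls_recommended = mi$p.value < alpha)
}

#' One-sample t-test of delta-transformed metrics against zero
#'
#' @param delta numeric vector of per-site delta values (>= 3 values with
#'   positive variance).
#' @return list: `mean`, `t`, `df`, `p`.
#' @export
deltaMeta <- function(delta) {
  if (length(delta) < 3) stop("need at least 3 values")
  if (sd(delta) == 0) stop("zero variance: t statistic undefined")
  tt <- t.test(delta, mu = 0)
  list(mean = unname(tt$estimate), t = unname(tt$statistic),
       df = unname(tt$parameter), p = tt$p.value)
}

#' Compare a network metric between taxonomic resolutions
#'
#' Pearson correlation plus a paired t-test of per-site metric values at
#' species versus genus resolution.
#'
#' @param species,genus numeric vectors of per-site metric values, paired
#'   by site.
#' @return list: `r`, `r_p`, `t`, `t_p`.
#' @export
resolutionCompare <- function(species, genus) {
  stopifnot(length(species) == length(genus), length(species) >= 3)
  ct <- cor.test(species, genus, method = "pearson")
  dif <- species - genus
  if (sd(dif) <= 1e-10 * max(1, abs(mean(dif)))) {
    if (abs(mean(dif)) <= 1e-12) {
      return(list(r = unname(ct$estimate), r_p = ct$p.value, t = 0, t_p = 1))
    }
    stop("constant non-zero paired difference: t undefined")
  }
  tt <- t.test(species, genus, paired = TRUE)
  list(r = unname(ct$estimate), r_p = ct$p.value,
       t = unname(tt$statistic), t_p = tt$p.value)
}
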