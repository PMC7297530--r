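## Cell-type assignment, L5 subtype clustering, thick-tuftedness PCA and
## the regression models relating synaptic composition to morphology.

.l5FeatureNames <- c("somaEquivDiameter", "bifurcationDepth", "nOblique",
                     "trunkDiameter")

#' Assign cortical layer from soma depth
#'
#' Interval lookup with half-open `[lo, hi)` boundaries: depths below the
#' first threshold are L2, below the second L3, below the third L5;
#' deeper somata are `"unknown"`. Dendrites without a soma in the volume
#' (`NA` depth) are deep-layer (`"DL"`).
#'
#' @param somaDepth numeric vector of soma depths below pia, micrometres
#'   (`NA` for somata outside the volume).
#' @param thresholds strictly increasing numeric length-3: L2/L3 boundary,
#'   L3/L5 boundary, maximum classifiable depth.
#' @return character vector of layer labels.
#' @export
assignLayer <- function(somaDepth, thresholds = c(150, 350, 800)) {
  stopifnot(length(thresholds) == 3, all(diff(thresholds) > 0))
  out <- rep("unknown", length(somaDepth))
  out[!is.na(somaDepth) & somaDepth < thresholds[1]] <- "L2"
  out[!is.na(somaDepth) & somaDepth >= thresholds[1] &
      somaDepth < thresholds[2]] <- "L3"
  out[!is.na(somaDepth) & somaDepth >= thresholds[2] &
      somaDepth < thresholds[3]] <- "L5"
  out[is.na(somaDepth)] <- "DL"
  out
}

#' Flag layer-2 marginal neurons by trunk orientation
#'
#' Marginal neurons sit at the L1/2 border with an oblique apical dendrite
#' running parallel to the pial surface. The trunk direction is estimated
#' as the chord from soma to main bifurcation; the flag is set when the
#' angle between the chord and the pia normal (the canonical depth axis
#' `z`) exceeds the threshold.
#'
#' @param ad a [DendriteAnnotation-class] with both landmarks set.
#' @param angleThreshold degrees from the pia normal.
#' @return logical.
#' @export
flagL2MN <- function(ad, angleThreshold = 60) {
  if (is.na(ad@somaNode) || is.na(ad@mainBifurcationNode))
    stop("soma and main bifurcation landmarks must be set", call. = FALSE)
  nd <- ad@tree@nodes
  s <- unlist(nd[match(ad@somaNode, nd$id), c("x", "y", "z")])
  b <- unlist(nd[match(ad@mainBifurcationNode, nd$id), c("x", "y", "z")])
  v <- b - s
  len <- sqrt(sum(v^2))
  if (len < 5)
    stop("cannot evaluate: soma-bifurcation chord shorter than 5 um",
         call. = FALSE)
  ## trunk ascends towards pia (negative z); angle to the depth axis
  cosang <- abs(v[3]) / len
  ang <- acos(pmin(1, pmax(-1, cosang))) * 180 / pi
  unname(ang > angleThreshold)
}

.featureMatrix <- function(features) {
  features <- as.data.frame(features)
  miss <- setdiff(.l5FeatureNames, names(features))
  if (length(miss))
    stop("missing L5 features: ", paste(miss, collapse = ", "),
         call. = FALSE)
  as.matrix(features[, .l5FeatureNames])
}

.cosineDist <- function(X) {
  nrm <- sqrt(rowSums(X^2))
  S <- (X %*% t(X)) / outer(nrm, nrm)
  stats::as.dist(1 - S)
}

#' Two-cluster partition of L5 pyramidal cells
#'
#' Agglomerative average-linkage clustering of the four morphological
#' features (soma equivalent diameter, main-bifurcation depth, oblique
#' dendrite count, trunk diameter), standardized to unit variance.
#' Candidate metrics (cosine, Euclidean, correlation, city-block) compete
#' on cophenetic correlation -- the agreement between pairwise distances
#' and dendrogram link heights -- and the winner's tree is cut into two
#' clusters. The cluster with the larger mean soma diameter is labelled
#' thick-tufted (`"L5tt"`), the other slender-tufted (`"L5st"`). A warning
#' is raised if cosine distance does not win the metric competition.
#'
#' @param features `data.frame` with the four feature columns (see
#'   [l5Features()] naming), at least 4 cells.
#' @param standardize scale features to unit variance first.
#' @return list with `labels` (character vector `"L5tt"`/`"L5st"`),
#'   `metric`, `copheneticCorrelation` (named vector over candidates), and
#'   `hclust` (the winning tree).
#' @export
clusterL5 <- function(features, standardize = TRUE) {
  X <- .featureMatrix(features)
  if (nrow(X) < 4)
    stop("need at least 4 cells to cluster", call. = FALSE)
  Xs <- if (standardize) scale(X) else X
  if (any(!is.finite(Xs)))
    stop("degenerate clustering: a feature has zero variance",
         call. = FALSE)
  dists <- list(
    cosine = .cosineDist(Xs),
    euclidean = stats::dist(Xs),
    correlation = stats::as.dist(1 - stats::cor(t(Xs))),
    cityblock = stats::dist(Xs, method = "manhattan"))
  if (max(dists$euclidean) < 1e-12)
    stop("degenerate clustering: identical feature vectors",
         call. = FALSE)
  cop <- vapply(dists, function(d) {
    h <- stats::hclust(d, method = "average")
    suppressWarnings(stats::cor(d, stats::cophenetic(h)))
  }, numeric(1))
  cop[is.na(cop)] <- -Inf
  winner <- names(cop)[which.max(cop)]
  if (winner != "cosine")
    warning("cosine distance did not maximize cophenetic correlation (",
            winner, " won)")
  h <- stats::hclust(dists[[winner]], method = "average")
  cl <- stats::cutree(h, k = 2)
  m1 <- mean(X[cl == 1, "somaEquivDiameter"])
  m2 <- mean(X[cl == 2, "somaEquivDiameter"])
  labels <- if (m1 >= m2) c("L5tt", "L5st")[cl] else c("L5st", "L5tt")[cl]
  list(labels = labels, metric = winner, copheneticCorrelation = cop,
       hclust = h)
}

#' Thick-tuftedness score (first principal component)
#'
#' PC1 of the standardized 4-D morphological feature space, sign-oriented
#' so that the score correlates positively with soma equivalent diameter.
#'
#' @param features `data.frame` with the four L5 feature columns; at least
#'   2 cells.
#' @return list with `scores` (PC1 per cell), `loadings`,
#'   `explainedVariance` (fraction of total variance on PC1).
#' @export
thickTuftedness <- function(features) {
  X <- .featureMatrix(features)
  if (nrow(X) < 2) stop("need at least 2 cells", call. = FALSE)
  sds <- apply(X, 2, stats::sd)
  if (any(sds == 0))
    stop("zero-variance feature: ", paste(
      colnames(X)[sds == 0], collapse = ", "), call. = FALSE)
  pc <- stats::prcomp(X, center = TRUE, scale. = TRUE)
  scores <- pc$x[, 1]
  loadings <- pc$rotation[, 1]
  if (stats::cor(scores, X[, "somaEquivDiameter"]) < 0) {
    scores <- -scores
    loadings <- -loadings
  }
  list(scores = unname(scores), loadings = loadings,
       explainedVariance = pc$sdev[1]^2 / sum(pc$sdev^2))
}

.fitResult <- function(model, params, rsq, n) {
  out <- list(model = model, params = params, rSquared = rsq, n = n)
  class(out) <- "FitResult"
  out
}

#' @export
print.FitResult <- function(x, ...) {
  cat("FitResult [", x$model, "]: ",
      paste(sprintf("%s = %.4g", names(x$params), x$params),
            collapse = ", "),
      "; R^2 = ", signif(x$rSquared, 4), ", n = ", x$n, "\n", sep = "")
  invisible(x)
}

.rsq <- function(y, fitted) {
  sstot <- sum((y - mean(y))^2)
  if (sstot == 0) return(0)
  1 - sum((y - fitted)^2) / sstot
}

#' Fit a single-term exponential model with offset
#'
#' Least squares fit of `y = c + a * exp(b * x)`. Initial values: `c` from
#' the minimum of `y`, `a` from the range, `b` from a log-linear
#' regression of `y - c`. When `y` lies in `[0, 1]` (a fraction), `c` is
#' bounded to that interval.
#'
#' @param x,y numeric vectors (at least 4 points).
#' @return A `"FitResult"` with `params` `a`, `b`, `c` and `rSquared`.
#' @examples
#' x <- seq(10, 330, length.out = 81)
#' f <- fitExponential(x, 1.57 * exp(-0.047 * x) + 0.1)
#' f$params
#' @export
fitExponential <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 4)
  if (stats::sd(y) == 0)
    return(.fitResult("exponential_offset",
                      c(a = 0, b = 0, c = mean(y)), 0, length(x)))
  c0 <- min(y) - 0.01 * diff(range(y))
  a0 <- max(y) - c0
  pos <- y - c0 > 0
  b0 <- tryCatch(unname(stats::coef(stats::lm(
    log(y[pos] - c0) ~ x[pos]))[2]), error = function(e) -0.01)
  if (!is.finite(b0) || b0 == 0) b0 <- -0.01
  isFraction <- all(y >= 0 & y <= 1)
  lower <- c(-Inf, -Inf, if (isFraction) 0 else -Inf)
  upper <- c(Inf, Inf, if (isFraction) 1 else Inf)
  fit <- NULL
  for (b0k in unique(c(b0, -0.01, -0.05, 0.01))) {
    fit <- tryCatch(
      minpack.lm::nlsLM(y ~ c + a * exp(b * x),
        start = list(a = a0, b = b0k, c = max(min(y), c0)),
        lower = lower, upper = upper,
        control = minpack.lm::nls.lm.control(maxiter = 500)),
      error = function(e) NULL)
    if (!is.null(fit)) break
  }
  if (is.null(fit))
    stop("exponential fit failed to converge", call. = FALSE)
  p <- stats::coef(fit)
  .fitResult("exponential_offset", c(a = unname(p["a"]),
                                     b = unname(p["b"]),
                                     c = unname(p["c"])),
             .rsq(y, stats::fitted(fit)), length(x))
}

#' Fit an ordinary linear model
#'
#' @param x,y numeric vectors (at least 3 points; `x` must vary).
#' @return A `"FitResult"` with `params` `a` (slope) and `b` (intercept).
#' @export
fitLinear <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 3)
  if (stats::sd(x) == 0)
    stop("zero variance in x", call. = FALSE)
  fit <- stats::lm(y ~ x)
  p <- stats::coef(fit)
  .fitResult("linear", c(a = unname(p[2]), b = unname(p[1])),
             .rsq(y, stats::fitted(fit)), length(x))
}

#' Fit a linear-fraction model
#'
#' Least squares fit of `y = (a x + b) / (c x + d)`. The model is
#' invariant to a common rescaling of the four parameters, so the
#' denominator intercept is normalized to `d = 1` during optimization
#' (the reported parameters are on that scale; the fitted curve is
#' identical for any common rescaling). Initial values come from the
#' linearization `y = a x + b - c x y`. The fit is rejected when the
#' fitted denominator changes sign over the data range.
#'
#' @param x,y numeric vectors (at least 5 points).
#' @return A `"FitResult"` with `params` `a`, `b`, `c`, `d` (with
#'   `d = 1`).
#' @export
fitLinearFraction <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 5)
  init <- stats::coef(stats::lm(y ~ x + I(-x * y)))
  st <- c(a = unname(init[2]), b = unname(init[1]), c = unname(init[3]))
  if (any(!is.finite(st))) st <- c(a = 0, b = mean(y), c = 0)
  fit <- tryCatch(
    minpack.lm::nlsLM(y ~ (a * x + b) / (c * x + 1), start = as.list(st),
      control = minpack.lm::nls.lm.control(maxiter = 500)),
    error = function(e) NULL)
  if (!is.null(fit)) {
    p <- stats::coef(fit)
  } else {
    ## degenerate Jacobian (e.g. exactly linear data): direct SSR descent
    ssr <- function(q) {
      den <- q[3] * x + 1
      if (any(abs(den) < 1e-8)) return(Inf)
      sum((y - (q[1] * x + q[2]) / den)^2)
    }
    op <- stats::optim(st, ssr, control = list(maxit = 2000,
                                               reltol = 1e-14))
    p <- stats::setNames(op$par, c("a", "b", "c"))
  }
  den <- p["c"] * range(x) + 1
  if (any(den <= 0))
    stop("fit rejected: denominator changes sign over the data range",
         call. = FALSE)
  yhat <- (p["a"] * x + p["b"]) / (p["c"] * x + 1)
  .fitResult("linear_fraction",
             c(a = unname(p["a"]), b = unname(p["b"]),
               c = unname(p["c"]), d = 1),
             .rsq(y, yhat), length(x))
}

#' Evaluate a fitted model at new x
#'
#' @param fit a `"FitResult"`.
#' @param x numeric vector.
#' @return fitted values.
#' @export
predictFit <- function(fit, x) {
  p <- fit$params
  switch(fit$model,
    exponential_offset = p["c"] + p["a"] * exp(p["b"] * x),
    linear = p["a"] * x + p["b"],
    linear_fraction = (p["a"] * x + p["b"]) / (p["c"] * x + p["d"]),
    stop("unknown model: ", fit$model)) |> unname()
}

#' Predict the inhibitory fraction from linear density fits
#'
#' Predicts the putative-inhibitory fraction as `I / (I + E)` where each
#' density is either its linear fit against `x` (thick-tuftedness) or its
#' sample mean, depending on `mode`: `"E_only"` models only the
#' excitatory density (inhibitory held at its mean), `"I_only"` the
#' reverse, `"combined"` models both. Explained variance is the R-squared
#' of the predicted against the observed fraction
#' `iDensity / (iDensity + eDensity)`.
#'
#' @param x numeric covariate (e.g. PC1 scores).
#' @param eDensity,iDensity observed synapse densities per cell.
#' @param mode one of `"combined"`, `"E_only"`, `"I_only"`.
#' @return list with `predicted`, `observed`, `explainedVariance`,
#'   `mode`.
#' @export
predictFractionFromDensities <- function(x, eDensity, iDensity,
    mode = c("combined", "E_only", "I_only")) {
  mode <- match.arg(mode)
  stopifnot(length(x) == length(eDensity),
            length(x) == length(iDensity))
  eHat <- if (mode %in% c("combined", "E_only"))
    predictFit(fitLinear(x, eDensity), x) else
    rep(mean(eDensity), length(x))
  iHat <- if (mode %in% c("combined", "I_only"))
    predictFit(fitLinear(x, iDensity), x) else
    rep(mean(iDensity), length(x))
  if (any(eHat + iHat <= 0))
    stop("predicted total density is non-positive", call. = FALSE)
  pred <- iHat / (iHat + eHat)
  obs <- iDensity / (iDensity + eDensity)
  list(predicted = pred, observed = obs,
       explainedVariance = .rsq(obs, pred), mode = mode)
}

#' Nonparametric group comparison
#'
#' Wilcoxon rank-sum for two groups; Kruskal-Wallis for three or more,
#' followed by Tukey's honestly-significant-difference post-hoc test on
#' the rank-transformed values.
#'
#' @param values numeric vector.
#' @param groups factor/character of the same length.
#' @return list with `test` name, `statistic`, `p`, and (for 3+ groups)
#'   `postHoc` (`data.frame` of pairwise comparisons with adjusted
#'   p-values).
#' @export
compareGroups <- function(values, groups) {
  groups <- as.factor(groups)
  if (any(table(groups) == 0) || nlevels(groups) < 2)
    stop("need at least two non-empty groups", call. = FALSE)
  if (nlevels(groups) == 2) {
    sp <- split(values, groups)
    wt <- stats::wilcox.test(sp[[1]], sp[[2]], exact = FALSE)
    return(list(test = "wilcoxon_rank_sum",
                statistic = unname(wt$statistic), p = wt$p.value,
                postHoc = NULL))
  }
  kw <- stats::kruskal.test(values, groups)
  tk <- stats::TukeyHSD(stats::aov(rank(values) ~ groups))$groups
  postHoc <- data.frame(comparison = rownames(tk),
                        diff = tk[, "diff"], pAdj = tk[, "p adj"],
                        row.names = NULL)
  list(test = "kruskal_wallis", statistic = unname(kw$statistic),
       p = kw$p.value, postHoc = postHoc)
}

#' Assemble the L5 morphological feature table
#'
#' Convenience constructor validating the four canonical feature columns.
#'
#' @param somaEquivDiameter,bifurcationDepth,nOblique,trunkDiameter
#'   numeric vectors of equal length (micrometres, micrometres below pia,
#'   count, micrometres).
#' @return `data.frame` with the canonical columns.
#' @export
l5Features <- function(somaEquivDiameter, bifurcationDepth, nOblique,
                       trunkDiameter) {
  stopifnot(all(somaEquivDiameter > 0), all(trunkDiameter > 0),
            all(nOblique >= 0))
  data.frame(somaEquivDiameter = somaEquivDiameter,
             bifurcationDepth = bifurcationDepth,
             nOblique = nOblique, trunkDiameter = trunkDiameter)
}
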