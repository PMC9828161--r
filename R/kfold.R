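#' K-fold cross-validated expected log predictive density
#'
#' Randomly partitions species into \code{K} folds (simple, unstratified,
#' seeded), refits the model on each training complement, and computes
#' each held-out species' log pointwise predictive density as the
#' log-mean over posterior draws of its binomial density. The held-out
#' species' phylogenetic effect is drawn, per posterior draw, from its
#' conditional multivariate-normal distribution given that draw's
#' training-species effects (the correlation matrix links held-out tips
#' to training tips).
#'
#' @param k named integer vector of counts per species.
#' @param X design matrix (rows match \code{k}; may have zero columns).
#' @param C phylogenetic correlation, or NULL for independent species.
#' @param trials binomial trials (default 5).
#' @param K number of folds (default 16); must not exceed the number of
#'   species.
#' @param seed seed controlling both the partition and the refits.
#' @param label model label.
#' @param ... sampler settings passed to [fitDichromatismModel()]
#'   (e.g. \code{chains}, \code{iter}).
#' @return list with \code{elpd}, \code{se}, \code{kfoldIC} (\eqn{-2 \cdot}
#'   elpd), \code{seIC}, \code{pointwise} (named per species),
#'   \code{folds} (fold id per species), \code{K}, \code{label}.
#' @export
kfoldElpd <- function(k, X = NULL, C = NULL, trials = 5, K = 16, seed = 1,
                      label = "model", ...) {
  n <- length(k)
  if (K > n) stop("K must not exceed the number of species", call. = FALSE)
  if (K < 2) stop("K must be at least 2", call. = FALSE)
  if (is.null(X)) X <- matrix(0, n, 0L)
  species <- names(k)
  if (is.null(species)) species <- sprintf("sp%03d", seq_len(n))
  set.seed(seed * 977L + 1L)
  folds <- sample(rep_len(seq_len(K), n))
  if (any(tabulate(folds, K) == 0L))
    stop("a fold has no test species", call. = FALSE)
  pointwise <- numeric(n)
  for (f in seq_len(K)) {
    test <- which(folds == f)
    train <- which(folds != f)
    fit <- fitDichromatismModel(
      setNames(k[train], species[train]),
      X[train, , drop = FALSE],
      if (!is.null(C)) C[train, train, drop = FALSE],
      trials = trials, seed = seed * 7919L + f, label = label, ...)
    draws <- fit@draws
    ndr <- nrow(draws)
    alpha <- draws[, "alpha"]
    etaFix <- alpha + (if (ncol(X))
      tcrossprod(draws[, colnames(X), drop = FALSE],
                 X[test, , drop = FALSE]) else 0)  # draws x n_test
    etaFix <- matrix(etaFix, nrow = ndr, ncol = length(test))
    if (fit@model$sampleSigma) {
      sig <- draws[, "sigma_phylo"]
      if (is.null(C)) {
        ## independent species: u_test ~ N(0, sigma^2)
        set.seed(seed * 104729L + f)
        uTest <- matrix(rnorm(ndr * length(test)), ndr) * sig
      } else {
        C11 <- C[train, train, drop = FALSE] + diag(1e-8, length(train))
        C21 <- C[test, train, drop = FALSE]
        A <- C21 %*% solve(C11)                      # n_test x n_train
        Schur <- C[test, test, drop = FALSE] - A %*% t(C21)
        Schur <- (Schur + t(Schur)) / 2
        Ls <- t(chol(Schur + diag(1e-8, nrow(Schur))))
        uTrain <- draws[, paste0("u.", species[train]), drop = FALSE]
        condMean <- uTrain %*% t(A)                  # draws x n_test
        set.seed(seed * 104729L + f)
        zr <- matrix(rnorm(ndr * length(test)), ndr)
        uTest <- condMean + (zr %*% t(Ls)) * sig
      }
      etaFix <- etaFix + uTest
    }
    for (j in seq_along(test)) {
      s <- test[j]
      lpdDraws <- dbinom(k[s], trials, invlogit(etaFix[, j]), log = TRUE)
      pointwise[s] <- logMeanExp(lpdDraws)
    }
  }
  names(pointwise) <- species
  elpd <- sum(pointwise)
  se <- sqrt(n * var(pointwise))
  list(elpd = elpd, se = se, kfoldIC = -2 * elpd, seIC = 2 * se,
       pointwise = pointwise, folds = setNames(folds, species),
       K = K, seed = seed, label = label)
}

#' Compare models by k-fold ELPD
#'
#' Differences in expected log pointwise predictive density against the
#' best model (set to 0); standard errors from the pointwise differences.
#' All results must share species and fold assignments (use the same
#' \code{seed}).
#'
#' @param results named list of [kfoldElpd()] results.
#' @return data.frame ordered best first with columns \code{model},
#'   \code{elpd}, \code{se}, \code{kfoldIC}, \code{seIC},
#'   \code{deltaElpd} (0 for the best, negative otherwise),
#'   \code{seDelta}.
#' @export
elpdCompare <- function(results) {
  if (length(results) < 2L) stop("need at least two models", call. = FALSE)
  if (is.null(names(results)))
    names(results) <- vapply(results, `[[`, "", "label")
  f0 <- results[[1L]]$folds
  for (r in results)
    if (!identical(r$folds, f0))
      stop("fold assignments differ between models; use a shared seed",
           call. = FALSE)
  elpds <- vapply(results, `[[`, 0, "elpd")
  best <- which.max(elpds)
  n <- length(f0)
  rows <- lapply(seq_along(results), function(i) {
    r <- results[[i]]
    dpw <- r$pointwise - results[[best]]$pointwise
    data.frame(model = names(results)[i], elpd = r$elpd, se = r$se,
               kfoldIC = r$kfoldIC, seIC = r$seIC,
               deltaElpd = sum(dpw),
               seDelta = if (i == best) 0 else sqrt(n * var(dpw)))
  })
  out <- do.call(rbind, rows)
  out <- out[order(-out$elpd), , drop = FALSE]
  rownames(out) <- NULL
  out
}
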