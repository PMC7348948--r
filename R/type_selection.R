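#' Functional-response type selection by polynomial logistic regression
#'
#' Fits a binomial logistic regression of the proportion killed on
#' polynomial terms of the initial density,
#' `cbind(killed, density - killed) ~ poly(density, degree, raw = TRUE)`,
#' the standard screen for the shape of a functional response: a
#' significantly negative linear coefficient indicates a type II
#' (monotonically declining kill proportion), a significantly positive
#' linear coefficient -- together with a negative higher-order term when
#' `degree >= 2` -- indicates a type III (initially rising proportion).
#'
#' The regression itself is an ordinary binomial GLM (iteratively
#' reweighted least squares); non-convergence or complete separation is
#' trapped and reported as an `inconclusive` classification rather than an
#' error, since downstream fitting should simply not proceed on such data.
#'
#' @param trials An [fr_trials] table.
#' @param degree Polynomial degree in density, 1, 2 or 3. The cubic screen
#'   is the classical recommendation; degree 2 is the default here since
#'   the linear and quadratic signs carry the classification.
#' @param alpha Significance level for classification; default 0.05.
#' @return An object of class `fr_type_test`: a coefficient table
#'   (`estimate`, `se`, `z`, `p` per term), the model deviance, a
#'   convergence flag, and `classification` from [fr_classify()] at
#'   `alpha`.
#' @examples
#' tab <- fr_simulate(fr_reference_params()[1, ], seed = 42)
#' fr_type_test(tab)
#' @export
fr_type_test <- function(trials, degree = 2L, alpha = 0.05) {
  if (!inherits(trials, "fr_trials")) trials <- fr_trials(trials)
  if (!degree %in% 1:3) stop("fr_type_test(): `degree` must be 1, 2 or 3")
  dat <- data.frame(killed = trials$killed,
                    alive = trials$density - trials$killed,
                    density = trials$density)
  ok <- TRUE
  fit <- withCallingHandlers(
    tryCatch(glm(cbind(killed, alive) ~ poly(density, degree, raw = TRUE),
                 family = binomial(), data = dat,
                 control = list(epsilon = 1e-10, maxit = 100)),
             error = function(e) NULL),
    warning = function(w) {
      ok <<- FALSE
      invokeRestart("muffleWarning")
    })
  if (is.null(fit) || !fit$converged) ok <- FALSE
  if (is.null(fit)) {
    res <- structure(list(table = NULL, degree = degree, converged = FALSE,
                          deviance = NA_real_, alpha = alpha,
                          classification = "inconclusive"),
                     class = "fr_type_test")
    return(res)
  }
  sm <- summary(fit)$coefficients
  tab <- data.frame(
    term = c("intercept", c("linear", "quadratic", "cubic")[seq_len(degree)]),
    estimate = sm[, 1], se = sm[, 2], z = sm[, 3], p = sm[, 4],
    row.names = NULL, stringsAsFactors = FALSE)
  res <- structure(list(table = tab, degree = degree, converged = ok,
                        deviance = deviance(fit), alpha = alpha,
                        classification = NA_character_),
                   class = "fr_type_test")
  res$classification <- fr_classify(res, alpha)
  res
}

#' Classify a functional response from a type-selection fit
#'
#' Decision rule on the polynomial logistic regression of [fr_type_test()]:
#' a significant negative linear coefficient gives `"type_II"`; a
#' significant positive linear coefficient gives `"type_III"`, where for
#' degree >= 2 a significant negative higher-order (quadratic or cubic)
#' term is additionally required so that the proportion killed eventually
#' declines; anything else -- including a fit flagged as non-converged --
#' is `"inconclusive"`.
#'
#' @param test An `fr_type_test` object.
#' @param alpha Significance level in (0, 1).
#' @return One of `"type_II"`, `"type_III"`, `"inconclusive"`.
#' @export
fr_classify <- function(test, alpha = 0.05) {
  if (!inherits(test, "fr_type_test")) {
    stop("fr_classify(): expected an `fr_type_test` object")
  }
  if (!is.numeric(alpha) || length(alpha) != 1L || alpha <= 0 || alpha >= 1) {
    stop("fr_classify(): `alpha` must be in (0, 1)")
  }
  if (!isTRUE(test$converged) || is.null(test$table)) return("inconclusive")
  tab <- test$table
  lin <- tab[tab$term == "linear", ]
  if (lin$p < alpha && lin$estimate < 0) return("type_II")
  if (lin$p < alpha && lin$estimate > 0) {
    if (test$degree == 1L) return("type_III")
    higher <- tab[tab$term %in% c("quadratic", "cubic"), ]
    if (any(higher$p < alpha & higher$estimate < 0)) return("type_III")
  }
  "inconclusive"
}

#' @export
print.fr_type_test <- function(x, digits = 4, ...) {
  cat("Functional-response type selection (polynomial degree ",
      x$degree, ")\n", sep = "")
  if (!is.null(x$table)) {
    print(cbind(x$table[1], round(x$table[-1], digits)), row.names = FALSE)
    cat("residual deviance:", format(x$deviance, digits = digits), "\n")
  }
  if (!x$converged) cat("NOTE: regression flagged as non-converged\n")
  cat("classification (alpha = ", x$alpha, "): ", x$classification,
      "\n", sep = "")
  invisible(x)
}
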