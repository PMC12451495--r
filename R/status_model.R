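#' Default status-transition model parameters
#'
#' Baseline odds and odds ratios used as the generating truth by the
#' synthetic status simulator: per non-reference outcome, an intercept on
#' the odds scale and one odds ratio per exposure class (heat wave,
#' drought, cold spell), each expressing the multiplicative change in the
#' odds of that outcome (vs. no change) as the exposure proportion goes
#' from 0 to 1.
#'
#' @return Named list with `uplisted` and `downlisted` components, each
#'   `c(intercept, heat, drought, cold)` on the odds / odds-ratio scale.
#' @export
default_status_params <- function() {
  list(uplisted   = c(intercept = 0.03, heat = 1.84, drought = 1.66, cold = 1.24),
       downlisted = c(intercept = 0.02, heat = 0.67, drought = 0.18, cold = 0.77))
}

#' Multinomial logistic regression of status change on exposure
#'
#' Fits a multinomial logit by full Newton iterations on the multinomial
#' log-likelihood with step-halving, using one outcome as the reference
#' (linear predictor fixed at 0). Standard errors are Wald, from the
#' inverse observed information at the maximum; coefficients are reported
#' both raw and exponentiated (odds ratios) with 95% Wald intervals.
#'
#' @param records Data frame with one row per species: the outcome column
#'   (factor or character) and numeric predictor columns.
#' @param predictors Character vector of predictor column names.
#' @param outcome Name of the outcome column.
#' @param reference Reference outcome level (default `"no_change"`).
#' @param max_iter Maximum Newton iterations (default 200).
#' @param tol Convergence tolerance on the gradient max-norm.
#' @return An object of class `status_fit`: coefficient matrix
#'   `(1 + p) x (K - 1)`, `vcov`, `se`, log-likelihood, iteration trace,
#'   convergence and separation flags, `n`.
#' @export
fit_status_model <- function(records,
                             predictors = c("heat_exposure", "drought_exposure",
                                            "cold_exposure"),
                             outcome = "outcome",
                             reference = "no_change",
                             max_iter = 200L, tol = 1e-8) {
  stopifnot(is.data.frame(records), outcome %in% names(records),
            all(predictors %in% names(records)))
  X <- as.matrix(cbind(`(Intercept)` = 1, records[predictors]))
  if (anyNA(X)) stop("missing predictor values", call. = FALSE)
  # a zero-variance exposure (e.g. no species overlaps that hazard layer at
  # all) carries no information and would make the model unidentifiable
  const <- vapply(predictors, function(p) stats::sd(records[[p]]) == 0, logical(1))
  dropped <- predictors[const]
  if (length(dropped)) {
    warning(sprintf("constant predictor(s) dropped: %s",
                    paste(dropped, collapse = ", ")), call. = FALSE)
    predictors <- predictors[!const]
    X <- as.matrix(cbind(`(Intercept)` = 1, records[predictors]))
  }
  y <- as.character(records[[outcome]])
  levs <- unique(y)
  if (!reference %in% levs)
    stop(sprintf("reference outcome '%s' absent from data", reference), call. = FALSE)
  levs <- c(reference, sort(setdiff(levs, reference)))
  if (length(levs) < 3L)
    warning("fewer than 3 outcome levels present; model degrades to a binary logit",
            call. = FALSE)
  if (length(levs) < 2L) stop("outcome has a single level", call. = FALSE)
  K <- length(levs); p <- ncol(X); n <- nrow(X)
  Y <- matrix(0, n, K - 1L)
  for (k in 2:K) Y[, k - 1L] <- as.numeric(y == levs[k])

  B <- matrix(0, p, K - 1L)      # coefficients for non-reference outcomes
  ll <- function(B) {
    eta <- X %*% B
    m <- pmax(apply(eta, 1, max), 0)
    sum(rowSums(Y * eta)) - sum(m + log(exp(-m) + rowSums(exp(eta - m))))
  }
  probs <- function(B) {
    eta <- X %*% B
    m <- pmax(apply(eta, 1, max), 0)
    den <- exp(-m) + rowSums(exp(eta - m))
    exp(eta - m) / den
  }
  ll_trace <- numeric(0)
  ll_cur <- ll(B)
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    P <- probs(B)
    G <- crossprod(X, Y - P)                       # p x (K-1) gradient
    if (max(abs(G)) < tol) { converged <- TRUE; break }
    info <- matrix(0, p * (K - 1L), p * (K - 1L))  # observed information
    for (a in seq_len(K - 1L)) for (b in seq_len(K - 1L)) {
      w <- if (a == b) P[, a] * (1 - P[, a]) else -P[, a] * P[, b]
      blk <- crossprod(X, X * w)
      info[(a - 1L) * p + 1:p, (b - 1L) * p + 1:p] <- blk
    }
    step <- tryCatch(solve(info, as.vector(G)),
                     error = function(e) stop("singular information matrix; model not identifiable",
                                              call. = FALSE))
    # step-halving keeps the log-likelihood non-decreasing
    lambda <- 1
    repeat {
      B_new <- B + matrix(lambda * step, p, K - 1L)
      ll_new <- ll(B_new)
      if (ll_new >= ll_cur - 1e-12 || lambda < 1e-8) break
      lambda <- lambda / 2
    }
    B <- B_new
    ll_cur <- ll_new
    ll_trace <- c(ll_trace, ll_cur)
  }
  if (!converged)
    stop(sprintf("no convergence after %d iterations (gradient max-norm %.3g)",
                 max_iter, max(abs(crossprod(X, Y - probs(B))))), call. = FALSE)

  separation <- max(abs(B)) > 15
  if (separation)
    warning("possible complete separation: very large coefficients; Wald intervals unreliable",
            call. = FALSE)
  P <- probs(B)
  info <- matrix(0, p * (K - 1L), p * (K - 1L))
  for (a in seq_len(K - 1L)) for (b in seq_len(K - 1L)) {
    w <- if (a == b) P[, a] * (1 - P[, a]) else -P[, a] * P[, b]
    info[(a - 1L) * p + 1:p, (b - 1L) * p + 1:p] <- crossprod(X, X * w)
  }
  V <- solve(info)
  se <- matrix(sqrt(diag(V)), p, K - 1L)
  dimnames(B) <- dimnames(se) <- list(colnames(X), levs[-1])
  structure(list(coefficients = B, se = se, vcov = V,
                 levels = levs, reference = reference,
                 predictors = predictors, logLik = ll_cur,
                 ll_trace = ll_trace, iterations = it,
                 converged = converged, separation = separation,
                 dropped = dropped, n = n),
            class = "status_fit")
}

#' @export
coef.status_fit <- function(object, ...) object$coefficients

#' @export
logLik.status_fit <- function(object, ...) {
  structure(object$logLik, df = length(object$coefficients), class = "logLik")
}

#' @export
vcov.status_fit <- function(object, ...) object$vcov

#' Odds-ratio table for a fitted status model
#'
#' One row per non-reference outcome and term, with the exponentiated
#' coefficient, 95% Wald confidence interval and two-sided Wald p-value —
#' the customary presentation of a multinomial status-change analysis.
#'
#' @param fit A `status_fit`.
#' @param conf_level Confidence level (default 0.95).
#' @return Data frame `outcome`, `term`, `estimate` (log scale),
#'   `odds_ratio`, `ci_low`, `ci_high`, `p_value`.
#' @export
or_table <- function(fit, conf_level = 0.95) {
  stopifnot(inherits(fit, "status_fit"))
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  B <- fit$coefficients; S <- fit$se
  out <- do.call(rbind, lapply(colnames(B), function(oc)
    data.frame(outcome = oc, term = rownames(B),
               estimate = B[, oc],
               odds_ratio = exp(B[, oc]),
               ci_low = exp(B[, oc] - z * S[, oc]),
               ci_high = exp(B[, oc] + z * S[, oc]),
               p_value = 2 * stats::pnorm(-abs(B[, oc] / S[, oc])))))
  rownames(out) <- NULL
  out
}

#' @export
print.status_fit <- function(x, ...) {
  cat(sprintf("<status_fit> %d obs, outcomes: %s (ref %s), logLik %.2f, %d iterations%s\n",
              x$n, paste(x$levels, collapse = "/"), x$reference, x$logLik,
              x$iterations, if (x$separation) " [separation flagged]" else ""))
  tab <- or_table(x)
  tab$odds_ratio <- round(tab$odds_ratio, 3)
  tab$ci_low <- round(tab$ci_low, 3); tab$ci_high <- round(tab$ci_high, 3)
  tab$p_value <- signif(tab$p_value, 3)
  print(tab[, c("outcome", "term", "odds_ratio", "ci_low", "ci_high", "p_value")],
        row.names = FALSE)
  invisible(x)
}

#' Per-outcome predicted probabilities
#'
#' Softmax over the linear predictors with the reference outcome's linear
#' predictor fixed at 0; rows sum to 1 exactly (up to float rounding).
#'
#' @param fit A `status_fit`, or a coefficient matrix `(1 + p) x (K - 1)`
#'   with a `levels` attribute.
#' @param newdata Data frame containing the predictor columns.
#' @return Matrix of probabilities, one column per outcome level
#'   (reference first).
#' @export
predict_probabilities <- function(fit, newdata) {
  stopifnot(inherits(fit, "status_fit"))
  X <- as.matrix(cbind(1, newdata[fit$predictors]))
  eta <- cbind(0, X %*% fit$coefficients)   # reference first
  m <- apply(eta, 1, max)
  P <- exp(eta - m) / rowSums(exp(eta - m))
  colnames(P) <- fit$levels
  P
}
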