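# Multinomial logistic analysis of behavioural types: log(p^w / p^W) is
# modelled against the treatment (or the plate), with a reference type W.
# Fitting is by Newton iterations on the multinomial log-likelihood with a
# step-halving safeguard; treatment effects are compared with Wald
# contrasts alpha_i^w - alpha_i'^w.

#' One-hot encode cage outcomes
#'
#' @param letters Character vector of behavioural letters.
#' @param categories Category universe, in order (default A-F).
#' @return An integer matrix, one row per cage, one column per category,
#'   exactly one 1 per row.
#' @export
encode_outcomes <- function(letters, categories = LETTERS[1:6]) {
  idx <- match(letters, categories)
  if (anyNA(idx))
    stop("unknown letter(s): ", paste(unique(letters[is.na(idx)]), collapse = ", "))
  z <- matrix(0L, nrow = length(letters), ncol = length(categories),
              dimnames = list(NULL, categories))
  z[cbind(seq_along(letters), idx)] <- 1L
  z
}

predictor_factor <- function(data, predictor) {
  switch(predictor,
    intercept = factor(rep("all", nrow(data))),
    treatment = {
      f <- factor(data$treatment)
      if ("Control" %in% levels(f)) f <- stats::relevel(f, "Control")
      f
    },
    plate = factor(data$plate),
    stop("predictor must be 'intercept', 'treatment' or 'plate'"))
}

#' Fit a multinomial logistic model of behavioural types
#'
#' Fits log(p^w / p^W) = mu^w + effect^w by maximum likelihood (Newton
#' iterations with step-halving; the likelihood never decreases across
#' iterations). Identifiability uses reference-category coding for the
#' types and first-level-zero coding for the predictor (the control
#' treatment, when present, is the baseline with effect 0). A zero cell in
#' the predictor x type table triggers a quasi-separation warning; a small
#' ridge penalty can be requested to stabilize such fits.
#'
#' @param data Data frame with columns `letter` and, as needed,
#'   `treatment` and `plate`.
#' @param predictor `"treatment"` (type probabilities depend on the
#'   treatment), `"plate"` (on the plate only) or `"intercept"`.
#' @param reference Reference category W (default: last category present).
#' @param ridge Ridge penalty on the coefficients (0 = plain ML; 1e-6
#'   recommended under quasi-separation).
#' @param max_iter,tol Newton iteration cap and relative log-likelihood
#'   convergence tolerance.
#' @return A `multinom_fit`: coefficients (predictor-design rows x
#'   non-reference categories), `vcov` (inverse observed information),
#'   `logLik`, `aic`, `categories`, `reference`, convergence diagnostics.
#' @export
fit_multinomial <- function(data, predictor = c("treatment", "plate", "intercept"),
                            reference = NULL, ridge = 0,
                            max_iter = 200, tol = 1e-12) {
  predictor <- match.arg(predictor)
  cats <- sort(unique(as.character(data$letter)))
  if (length(cats) < 2) stop("need at least 2 observed categories")
  reference <- reference %||% cats[length(cats)]
  if (!reference %in% cats) stop("reference category not observed in the data")
  nonref <- setdiff(cats, reference)
  pred <- predictor_factor(data, predictor)
  X <- if (nlevels(pred) == 1) {
    matrix(1, nrow = nrow(data), ncol = 1, dimnames = list(NULL, "(Intercept)"))
  } else {
    m <- stats::model.matrix(~pred)
    colnames(m) <- sub("^pred", "", colnames(m))
    m
  }
  n <- nrow(X); p <- ncol(X); C1 <- length(nonref)
  Y <- encode_outcomes(data$letter, cats)[, nonref, drop = FALSE]

  cell <- table(pred, factor(data$letter, levels = cats))
  separated <- any(cell == 0)
  if (separated)
    warning("zero cell(s) in the predictor x type table: quasi-separation, ",
            "coefficients may be unstable (consider ridge = 1e-6)", call. = FALSE)

  loglik <- function(B) {
    eta <- X %*% B
    m <- pmax(apply(eta, 1, max), 0)
    logdenom <- m + log(exp(-m) + rowSums(exp(eta - m)))
    sum(rowSums(Y * eta)) - sum(logdenom)
  }
  probs <- function(B) {
    eta <- X %*% B
    m <- pmax(apply(eta, 1, max), 0)
    e <- exp(eta - m)
    denom <- exp(-m) + rowSums(e)
    e / denom
  }

  B <- matrix(0, nrow = p, ncol = C1, dimnames = list(colnames(X), nonref))
  ll <- loglik(B) - 0.5 * ridge * sum(B^2)
  converged <- FALSE
  iter <- 0
  repeat {
    iter <- iter + 1
    P <- probs(B)
    G <- crossprod(X, Y - P) - ridge * B          # p x C1 score
    H <- matrix(0, p * C1, p * C1)
    for (a in seq_len(C1)) for (b in seq_len(a)) {
      w <- if (a == b) P[, a] * (1 - P[, a]) else -P[, a] * P[, b]
      blk <- crossprod(X, X * w)
      ra <- (a - 1) * p + seq_len(p); rb <- (b - 1) * p + seq_len(p)
      H[ra, rb] <- blk
      H[rb, ra] <- t(blk)
    }
    H <- H + ridge * diag(p * C1)
    step <- tryCatch(solve(H, as.vector(G)), error = function(e)
      stop("singular information matrix (complete separation?): ",
           conditionMessage(e), call. = FALSE))
    lam <- 1
    repeat {
      B_new <- B + lam * matrix(step, nrow = p)
      ll_new <- loglik(B_new) - 0.5 * ridge * sum(B_new^2)
      if (ll_new >= ll - 1e-10 || lam < 1e-10) break
      lam <- lam / 2
    }
    improved <- ll_new - ll
    B <- B_new; ll <- ll_new
    if (max(abs(G)) < 1e-8 || abs(improved) < tol * max(1, abs(ll))) {
      converged <- TRUE
      break
    }
    if (iter >= max_iter) break
  }
  if (!converged)
    stop(sprintf("multinomial fit did not converge in %d iterations (max |score| %.3g, logLik %.6g)",
                 max_iter, max(abs(G)), ll))
  P <- probs(B)
  H <- matrix(0, p * C1, p * C1)
  for (a in seq_len(C1)) for (b in seq_len(a)) {
    w <- if (a == b) P[, a] * (1 - P[, a]) else -P[, a] * P[, b]
    blk <- crossprod(X, X * w)
    ra <- (a - 1) * p + seq_len(p); rb <- (b - 1) * p + seq_len(p)
    H[ra, rb] <- blk
    H[rb, ra] <- t(blk)
  }
  H <- H + ridge * diag(p * C1)
  vc <- tryCatch(solve(H), error = function(e) {
    warning("degenerate information matrix: covariance unavailable", call. = FALSE)
    matrix(NA_real_, p * C1, p * C1)
  })
  ll_plain <- loglik(B)
  k <- p * C1
  structure(list(coefficients = B, vcov = vc, logLik = ll_plain,
                 aic = 2 * k - 2 * ll_plain, n_params = k, n = n,
                 categories = cats, reference = reference,
                 predictor = predictor, levels = levels(pred),
                 design_cols = colnames(X), ridge = ridge,
                 iterations = iter, converged = converged,
                 separated = separated),
            class = "multinom_fit")
}

#' @export
print.multinom_fit <- function(x, ...) {
  cat(sprintf("multinomial logistic fit: %s model, %d obs, %d categories (reference %s)\n",
              x$predictor, x$n, length(x$categories), x$reference))
  cat(sprintf("logLik %.4f, AIC %.4f (%d parameters), %d Newton iterations\n",
              x$logLik, x$aic, x$n_params, x$iterations))
  invisible(x)
}

#' @export
logLik.multinom_fit <- function(object, ...) {
  structure(object$logLik, df = object$n_params, nobs = object$n,
            class = "logLik")
}

#' Akaike information criterion of a multinomial fit
#'
#' AIC = 2 k - 2 logLik with k = (categories - 1) x predictor design
#' columns.
#'
#' @param fit A `multinom_fit`.
#' @return The AIC.
#' @export
aic <- function(fit) fit$aic

#' Compare two multinomial fits by AIC
#'
#' Returns the fit with the smaller AIC; on a tie, the one with fewer
#' parameters.
#'
#' @param fit_a,fit_b Converged `multinom_fit`s on the same observations.
#' @return The chosen fit, with a `"chosen"` attribute naming its
#'   predictor.
#' @export
compare_models <- function(fit_a, fit_b) {
  if (fit_a$n != fit_b$n) stop("fits are not on the same number of observations")
  pick <- if (fit_a$aic < fit_b$aic) fit_a
          else if (fit_b$aic < fit_a$aic) fit_b
          else if (fit_a$n_params <= fit_b$n_params) fit_a else fit_b
  attr(pick, "chosen") <- pick$predictor
  pick
}

#' Estimated type probabilities per predictor level
#'
#' p-hat^w = e^(mu^w + alpha^w) / (1 + sum_v e^(mu^v + alpha^v)) per level,
#' with the reference category taking 1 / (1 + sum). Rows sum to 1.
#'
#' @param fit A `multinom_fit`.
#' @return A matrix, one row per predictor level, one column per category
#'   (in category order).
#' @export
estimate_probabilities <- function(fit) {
  lv <- fit$levels
  Xl <- if (length(lv) == 1) matrix(1, 1, 1)
        else stats::model.matrix(~f, data.frame(f = factor(lv, levels = lv)))
  eta <- Xl %*% fit$coefficients
  e <- exp(eta)
  denom <- 1 + rowSums(e)
  out <- cbind(e / denom, 1 / denom)
  colnames(out) <- c(colnames(fit$coefficients), fit$reference)
  out <- out[, fit$categories, drop = FALSE]
  rownames(out) <- lv
  out
}

# index of coefficient (design column d, non-reference category w) in the
# flattened (column-major over categories) parameter vector
coef_index <- function(fit, d, w) {
  p <- length(fit$design_cols)
  wi <- match(w, colnames(fit$coefficients))
  di <- match(d, fit$design_cols)
  if (is.na(wi) || is.na(di)) return(NA_integer_)
  (wi - 1L) * p + di
}

# contrast vector picking alpha_i^w (0 for the baseline level whose effect
# is absorbed in the intercept)
alpha_vector <- function(fit, i, w) {
  v <- numeric(length(fit$design_cols) * ncol(fit$coefficients))
  if (i == fit$levels[1]) return(v)   # baseline: alpha = 0
  idx <- coef_index(fit, i, w)
  if (is.na(idx)) stop("unknown treatment level: ", i)
  v[idx] <- 1
  v
}

#' Wald contrast between two treatments for one behavioural type
#'
#' estimate = alpha_i^w - alpha_i'^w; its standard error comes from the
#' coefficient covariance; z = estimate / SE with a two-sided normal
#' p-value. A positive estimate means type w (relative to the reference
#' type) is more frequent under treatment `i` than under `i_prime`.
#'
#' @param fit A converged `multinom_fit` (treatment or plate model).
#' @param w Behavioural type (non-reference category).
#' @param i,i_prime Predictor levels to contrast.
#' @return A one-row data frame: `type`, `i`, `i_prime`, `estimate`, `se`,
#'   `z`, `p`.
#' @export
wald_contrast <- function(fit, w, i, i_prime) {
  if (!w %in% colnames(fit$coefficients))
    stop("type must be a non-reference category: ",
         paste(colnames(fit$coefficients), collapse = ", "))
  if (!all(c(i, i_prime) %in% fit$levels)) stop("unknown predictor level")
  if (identical(i, i_prime))
    return(data.frame(type = w, i = i, i_prime = i_prime,
                      estimate = 0, se = 0, z = 0, p = 1))
  cvec <- alpha_vector(fit, i, w) - alpha_vector(fit, i_prime, w)
  est <- sum(cvec * as.vector(fit$coefficients))
  v <- drop(t(cvec) %*% fit$vcov %*% cvec)
  if (!is.finite(v) || v <= 0) stop("degenerate covariance for this contrast")
  se <- sqrt(v)
  z <- est / se
  data.frame(type = w, i = i, i_prime = i_prime, estimate = est, se = se,
             z = z, p = 2 * stats::pnorm(-abs(z)))
}

#' All pairwise Wald contrasts
#'
#' @param fit A converged `multinom_fit`.
#' @param adjust P-value adjustment method (see [stats::p.adjust()];
#'   `"none"` reproduces raw contrasts).
#' @return A data frame of contrasts for every non-reference type and
#'   every ordered pair of predictor levels, with column `p_adj`.
#' @export
all_contrasts <- function(fit, adjust = "none") {
  lv <- fit$levels
  if (length(lv) < 2)
    return(data.frame(type = character(0), i = character(0),
                      i_prime = character(0), estimate = numeric(0),
                      se = numeric(0), z = numeric(0), p = numeric(0),
                      p_adj = numeric(0)))
  pairs <- utils::combn(lv, 2, simplify = FALSE)
  out <- do.call(rbind, lapply(colnames(fit$coefficients), function(w)
    do.call(rbind, lapply(pairs, function(pr)
      wald_contrast(fit, w, pr[2], pr[1])))))
  out$p_adj <- stats::p.adjust(out$p, method = adjust)
  out
}

#' Choose the reference behavioural type
#'
#' The best reference is the category whose observations are most equally
#' distributed across the treatments: among categories with no zero
#' treatment cell, the one minimizing the chi-square statistic of its
#' per-treatment counts against uniformity (ties: alphabetical). If every
#' category has a zero cell, the most frequent category is used, with a
#' warning.
#'
#' @param data Data frame with columns `letter` and `treatment`.
#' @return The chosen category (character).
#' @export
choose_reference <- function(data) {
  tab <- table(data$treatment, data$letter)
  cats <- colnames(tab)
  ok <- cats[colSums(tab == 0) == 0]
  if (length(ok) == 0) {
    warning("every category has a zero treatment cell; falling back to the most frequent category",
            call. = FALSE)
    return(cats[which.max(colSums(tab))])
  }
  stat <- vapply(ok, function(cc) {
    x <- tab[, cc]
    e <- mean(x)
    sum((x - e)^2 / e)
  }, numeric(1))
  ok[order(stat, ok)][1]
}
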