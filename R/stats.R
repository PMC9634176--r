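#' Assemble a longitudinal visit table
#'
#' Long-format table of per-visit metrics across timepoints and conditions:
#' one value per (subject, timepoint, condition, metric).
#'
#' @param subject_id,timepoint,condition,metric,value equal-length vectors.
#' @return A `longitudinal_table` data frame.
#' @export
longitudinal_table <- function(subject_id, timepoint, condition, metric, value) {
  df <- data.frame(subject_id = as.character(subject_id),
                   timepoint = as.character(timepoint),
                   condition = as.character(condition),
                   metric = as.character(metric),
                   value = as.numeric(value), stringsAsFactors = FALSE)
  key <- paste(df$subject_id, df$timepoint, df$condition, df$metric, sep = "\r")
  if (anyDuplicated(key))
    stop("duplicate (subject, timepoint, condition, metric) cells")
  df <- df[order(df$subject_id, df$timepoint, df$condition, df$metric), ]
  rownames(df) <- NULL
  class(df) <- c("longitudinal_table", "data.frame")
  df
}

gee_family <- function(family) {
  switch(family,
         gaussian = list(linkinv = identity,
                         mu_eta = function(eta) rep(1, length(eta)),
                         varfun = function(mu) rep(1, length(mu))),
         poisson = list(linkinv = exp, mu_eta = exp, varfun = identity),
         stop("unsupported family: ", family))
}

#' Repeated-measures marginal-model effects (GEE)
#'
#' Fits a generalized estimating equation (Liang–Zeger) marginal model of
#' one metric on age (timepoint) and, optionally, condition with their
#' interaction, clustering on subject with an exchangeable working
#' correlation by default. Each factor is tested with a robust
#' (sandwich-covariance) Wald chi-square statistic; because that
#' covariance is estimated from finitely many clusters, p-values use the
#' better-calibrated `F(df, K - p)` reference (K clusters, p model
#' coefficients) rather than the anti-conservative asymptotic chi-square.
#' All pairwise level contrasts of each factor — on estimated marginal
#' means averaged over the other factor — are reported with
#' Bonferroni-adjusted p-values (t reference, same denominator df).
#'
#' @param table a [longitudinal_table()] (or data frame with the same
#'   columns).
#' @param metric which metric to model.
#' @param factors `"timepoint"`, or `c("timepoint", "condition")` (the
#'   interaction is included automatically with both).
#' @param family `"gaussian"` (identity link; durations, frequencies,
#'   coherence) or `"poisson"` (log link; counts).
#' @param corstr working correlation: `"exchangeable"`, `"independence"`,
#'   or `"ar1"` (AR(1) over the within-subject ordering).
#' @param max_iter,tol scoring-iteration controls.
#' @return An `effect_report`: coefficients, robust covariance, scale and
#'   working-correlation estimates, per-factor Wald tests (`effects`), and
#'   Bonferroni pairwise contrasts (`pairwise`).
#' @export
fit_repeated_effects <- function(table, metric,
                                 factors = c("timepoint", "condition"),
                                 family = c("gaussian", "poisson"),
                                 corstr = c("exchangeable", "independence", "ar1"),
                                 max_iter = 100, tol = 1e-10) {
  family <- match.arg(family)
  corstr <- match.arg(corstr)
  factors <- match.arg(factors, c("timepoint", "condition"),
                       several.ok = TRUE)
  df <- as.data.frame(table)
  df <- df[df$metric == metric & !is.na(df$value), , drop = FALSE]
  if (!nrow(df)) stop("no rows for metric: ", metric)
  for (f in factors) {
    lev <- sort(unique(df[[f]]))
    if (length(lev) < 2) stop("factor ", f, " has fewer than 2 levels")
    cnt <- base::table(df[[f]])
    if (any(cnt == 0))
      stop("factor level with no data: ", names(cnt)[cnt == 0][1])
    df[[f]] <- factor(df[[f]], levels = lev)
  }
  df <- df[order(df$subject_id, df$timepoint), , drop = FALSE]
  n_t <- length(unique(df$subject_id))
  tp_per_subj <- tapply(df$timepoint, df$subject_id,
                        function(z) length(unique(z)))
  if (sum(tp_per_subj >= 2) < 2)
    stop("need at least 2 subjects with at least 2 timepoints")

  fml <- if (length(factors) == 2) value ~ timepoint * condition
         else stats::as.formula(paste("value ~", factors))
  mf <- stats::model.frame(fml, df)
  X <- stats::model.matrix(fml, mf)
  y <- stats::model.response(mf)
  p <- ncol(X)
  fam <- gee_family(family)
  cl <- split(seq_len(nrow(df)), df$subject_id, drop = TRUE)

  beta <- stats::glm.fit(X, y, family = if (family == "poisson")
    stats::poisson() else stats::gaussian())$coefficients
  beta[is.na(beta)] <- 0
  alpha <- 0
  phi <- 1
  N <- length(y)
  for (iter in seq_len(max_iter)) {
    eta <- drop(X %*% beta)
    mu <- fam$linkinv(eta)
    vmu <- fam$varfun(mu)
    r <- (y - mu) / sqrt(vmu)
    phi <- max(sum(r^2) / (N - p), 1e-12)  # guard: exactly constant data
    if (corstr == "exchangeable") {
      num <- 0; den <- 0
      for (ix in cl) {
        ni <- length(ix)
        if (ni < 2) next
        s <- sum(r[ix])
        num <- num + (s^2 - sum(r[ix]^2)) / 2
        den <- den + ni * (ni - 1) / 2
      }
      alpha <- if (den > p) num / ((den - p) * phi) else 0
      nmax <- max(lengths(cl))
      alpha <- min(max(alpha, -0.95 / max(1, nmax - 1)), 0.99)
    } else if (corstr == "ar1") {
      num <- 0; den <- 0
      for (ix in cl) {
        ni <- length(ix)
        if (ni < 2) next
        num <- num + sum(r[ix][-ni] * r[ix][-1])
        den <- den + ni - 1
      }
      alpha <- if (den > p) num / ((den - p) * phi) else 0
      alpha <- min(max(alpha, -0.99), 0.99)
    }
    B <- matrix(0, p, p)
    U <- numeric(p)
    M <- matrix(0, p, p)
    for (ix in cl) {
      ni <- length(ix)
      R <- switch(corstr,
                  independence = diag(ni),
                  exchangeable = matrix(alpha, ni, ni) + diag(1 - alpha, ni),
                  ar1 = alpha^abs(outer(seq_len(ni), seq_len(ni), `-`)))
      Ah <- sqrt(vmu[ix])
      Vi <- phi * (R * outer(Ah, Ah))
      Di <- X[ix, , drop = FALSE] * fam$mu_eta(eta[ix])
      Vd <- solve(Vi, Di)
      ei <- y[ix] - mu[ix]
      B <- B + crossprod(Di, Vd)
      U <- U + drop(crossprod(Vd, ei))
      gi <- drop(crossprod(Vd, ei))
      M <- M + tcrossprod(gi)
    }
    delta <- solve(B, U)
    beta <- beta + delta
    if (sqrt(sum(delta^2)) < tol * (sqrt(sum(beta^2)) + tol)) break
  }
  Binv <- solve(B)
  V <- Binv %*% M %*% Binv

  trm <- stats::terms(fml)
  term_labels <- attr(trm, "term.labels")
  asgn <- attr(X, "assign")
  effects <- do.call(rbind, lapply(seq_along(term_labels), function(k) {
    cols <- which(asgn == k)
    b <- beta[cols]
    # a singular robust covariance block with a ~zero coefficient block is
    # the no-signal degenerate case (constant data): report W = 0, p = 1
    W <- tryCatch(drop(crossprod(b, solve(V[cols, cols, drop = FALSE], b))),
                  error = function(e)
                    if (max(abs(b)) < 1e-8) 0 else NA_real_)
    q <- length(cols)
    # p-value from an F(q, K - p) reference rather than chi-square(q):
    # the sandwich covariance is estimated from finitely many clusters and
    # the plain chi-square reference is anti-conservative
    df2 <- max(n_t - p, 1)
    data.frame(factor = term_labels[k], wald_chisq = W, df = q,
               p = stats::pf(W / q, q, df2, lower.tail = FALSE),
               stringsAsFactors = FALSE)
  }))

  xlev <- lapply(factors, function(f) levels(df[[f]]))
  names(xlev) <- factors
  grid <- expand.grid(xlev, stringsAsFactors = FALSE)
  for (f in factors) grid[[f]] <- factor(grid[[f]], levels = xlev[[f]])
  MMg <- stats::model.matrix(stats::delete.response(trm), grid)
  pairwise <- do.call(rbind, lapply(factors, function(f) {
    lev <- xlev[[f]]
    Lrows <- lapply(lev, function(l)
      colMeans(MMg[grid[[f]] == l, , drop = FALSE]))
    prs <- utils::combn(length(lev), 2)
    m <- ncol(prs)
    do.call(rbind, lapply(seq_len(m), function(j) {
      L <- Lrows[[prs[1, j]]] - Lrows[[prs[2, j]]]
      est <- drop(L %*% beta)
      se <- sqrt(max(drop(L %*% V %*% L), 0))
      z <- if (se < 1e-12) { if (abs(est) < 1e-8) 0 else sign(est) * Inf
      } else est / se
      praw <- 2 * stats::pt(-abs(z), max(n_t - p, 1))
      data.frame(factor = f, level1 = lev[prs[1, j]], level2 = lev[prs[2, j]],
                 estimate = est, se = se, z = z, p = praw,
                 p_adj = min(1, praw * m), stringsAsFactors = FALSE)
    }))
  }))

  structure(list(metric = metric, family = family, corstr = corstr,
                 coefficients = stats::setNames(beta, colnames(X)),
                 vcov_robust = V, alpha = alpha, phi = phi,
                 effects = effects, pairwise = pairwise,
                 n_subjects = n_t, n_obs = N, n_iter = iter),
            class = "effect_report")
}

#' @export
print.effect_report <- function(x, ...) {
  cat(sprintf("<effect_report> metric '%s' (%s, %s working correlation; %d subjects, %d obs)\n",
              x$metric, x$family, x$corstr, x$n_subjects, x$n_obs))
  cat("Wald tests:\n")
  print(x$effects, row.names = FALSE, digits = 4)
  cat("Pairwise (Bonferroni):\n")
  print(x$pairwise, row.names = FALSE, digits = 4)
  invisible(x)
}

#' Frame-level inter-rater agreement (Cohen's kappa)
#'
#' Rasterizes both coders' tracks to frame-level binary labels (rattling vs
#' not, at the video frame rate) and computes the chance-corrected
#' agreement `kappa = (p_o - p_e) / (1 - p_e)`, where `p_o` is the observed
#' frame agreement and `p_e` the chance agreement implied by the marginal
#' label frequencies.
#'
#' @param track_a,track_b [annotation_track()]s over the same recording.
#' @param fs frame rate in Hz (video default 25).
#' @param extent_s common extent in seconds; defaults to the latest offset
#'   in either track.
#' @param tier which tier to compare.
#' @return Kappa in `[-1, 1]`, or `NA` with a warning when both raters are
#'   constant with the same label (chance agreement 1, kappa undefined).
#' @export
cohens_kappa <- function(track_a, track_b, fs = 25, extent_s = NULL,
                         tier = "RATTLING") {
  stopifnot(inherits(track_a, "annotation_track"),
            inherits(track_b, "annotation_track"))
  if (is.null(extent_s))
    extent_s <- max(track_a$offset_s, track_b$offset_s)
  a <- binarize_annotations(track_a, tier, fs, extent_s)
  b <- binarize_annotations(track_b, tier, fs, extent_s)
  p_o <- mean(a == b)
  pa <- mean(a); pb <- mean(b)
  p_e <- pa * pb + (1 - pa) * (1 - pb)
  if (p_e >= 1 - .Machine$double.eps * 4) {
    warning("both raters constant with the same label: kappa undefined")
    return(NA_real_)
  }
  (p_o - p_e) / (1 - p_e)
}
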