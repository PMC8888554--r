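#' Fit a single-response OPLS model
#'
#' Orthogonal projections to latent structures regression of a numeric
#' response (here: sample depth) on a feature matrix. Columns of `X` are
#' mean-centred and (by default) unit-variance scaled; `n_ortho`
#' y-orthogonal components are extracted and removed, followed by one
#' predictive component. With `n_ortho = 0` the fit reduces to
#' single-component PLS1.
#'
#' @param X numeric matrix, samples x features.
#' @param y numeric response vector.
#' @param n_ortho number of orthogonal components (default 1).
#' @param scale `"uv"` (unit variance, default) or `"center"` only.
#' @return an object of class `opls_model`: weights/loadings/scores for
#'   the predictive and orthogonal components, scaling vectors, `R2X`,
#'   `R2Y`, fitted values and VIP scores.
#' @export
fit_opls <- function(X, y, n_ortho = 1, scale = c("uv", "center")) {
  scale <- match.arg(scale)
  X <- as.matrix(X)
  check_flag(nrow(X) >= 4, "need >= 4 samples (got %d)", nrow(X))
  check_flag(nrow(X) == length(y), "X rows must match length(y)")
  check_flag(sd(y) > 0, "constant response y")
  check_flag(!anyNA(X), "X contains missing values")
  rk <- qr(scale(X, scale = FALSE))$rank
  check_flag(n_ortho < rk,
             "n_ortho = %d must be below rank(X) = %d", n_ortho, rk)

  x_mean <- colMeans(X)
  x_sd <- if (scale == "uv") apply(X, 2, sd) else rep(1, ncol(X))
  x_sd[x_sd == 0] <- 1
  Xs <- sweep(sweep(X, 2, x_mean), 2, x_sd, "/")
  y_mean <- mean(y)
  ys <- y - y_mean
  ssx_total <- sum(Xs^2)

  W_o <- P_o <- NULL
  T_o <- NULL
  Xd <- Xs
  ssx_ortho <- 0
  for (a in seq_len(n_ortho)) {
    w <- crossprod(Xd, ys)[, 1]
    w <- w / sqrt(sum(w^2))
    t <- Xd %*% w
    p <- crossprod(Xd, t)[, 1] / sum(t^2)
    wo <- p - sum(w * p) * w
    nwo <- sqrt(sum(wo^2))
    if (nwo < 1e-12) break   # no orthogonal variation left
    wo <- wo / nwo
    to <- Xd %*% wo
    po <- crossprod(Xd, to)[, 1] / sum(to^2)
    Xd <- Xd - to %*% t(po)
    ssx_ortho <- ssx_ortho + sum((to %*% t(po))^2)
    W_o <- cbind(W_o, wo); P_o <- cbind(P_o, po); T_o <- cbind(T_o, to)
  }

  w <- crossprod(Xd, ys)[, 1]
  w <- w / sqrt(sum(w^2))
  t_p <- Xd %*% w
  p_p <- crossprod(Xd, t_p)[, 1] / sum(t_p^2)
  q <- sum(ys * t_p) / sum(t_p^2)
  fitted_s <- t_p * q
  r2y <- 1 - sum((ys - fitted_s)^2) / sum(ys^2)
  r2x <- (sum((t_p %*% t(p_p))^2) + ssx_ortho) / ssx_total

  # VIP on the predictive component: sqrt(p) * |w| (mean of VIP^2 is 1).
  vip <- sqrt(length(w)) * abs(w)

  structure(list(
    w_pred = w, p_pred = p_p, t_pred = t_p[, 1], q = q,
    W_ortho = W_o, P_ortho = P_o, T_ortho = T_o,
    n_ortho = if (is.null(T_o)) 0L else ncol(T_o),
    x_mean = x_mean, x_sd = x_sd, y_mean = y_mean,
    R2X = r2x, R2Y = r2y,
    fitted = fitted_s[, 1] + y_mean,
    vip = setNames(vip, colnames(X)),
    Q2 = NULL, pQ2 = NULL
  ), class = "opls_model")
}

#' @export
print.opls_model <- function(x, ...) {
  cat(sprintf("<opls_model> 1 predictive + %d orthogonal; R2X=%.3f R2Y=%.3f%s%s\n",
              x$n_ortho, x$R2X, x$R2Y,
              if (!is.null(x$Q2)) sprintf(" Q2=%.3f", x$Q2) else "",
              if (!is.null(x$pQ2)) sprintf(" pQ2=%.3g", x$pQ2) else ""))
  invisible(x)
}

#' Predict from an OPLS model
#' @param object an `opls_model`.
#' @param newdata samples x features matrix on the original scale.
#' @param ... unused.
#' @return numeric vector of predicted responses.
#' @export
predict.opls_model <- function(object, newdata, ...) {
  Xs <- sweep(sweep(as.matrix(newdata), 2, object$x_mean), 2, object$x_sd, "/")
  if (object$n_ortho > 0) {
    for (a in seq_len(object$n_ortho)) {
      to <- Xs %*% object$W_ortho[, a]
      Xs <- Xs - to %*% t(object$P_ortho[, a])
    }
  }
  t_p <- Xs %*% object$w_pred
  (t_p * object$q)[, 1] + object$y_mean
}

#' VIP scores of a fitted OPLS model
#'
#' Variable influence on projection, computed on the predictive
#' (orthogonal-filtered) component: `VIP_j = sqrt(p) * |w_j|` with `w` the
#' unit predictive weight vector, so the squared scores average exactly 1.
#'
#' @param model a fitted `opls_model`.
#' @return named numeric vector of VIP scores.
#' @export
vip_scores <- function(model) {
  check_flag(inherits(model, "opls_model"), "not a fitted opls_model")
  model$vip
}

# Seeded partition of n samples into k near-equal folds.
make_folds <- function(n, k, seed) {
  with_seed(seed, {
    idx <- sample(n)
    split(idx, rep(seq_len(k), length.out = n)[order(order(idx))])
  })
}

#' Cross-validated Q2 of an OPLS model
#'
#' k-fold (default seven-fold) cross-validation:
#' Q2 = 1 - PRESS / TSS, with centring/scaling re-estimated inside every
#' training fold. Fold assignment is a seeded random partition; `k = n`
#' gives leave-one-out.
#'
#' @param X samples x features matrix.
#' @param y response vector.
#' @param k number of folds (default 7).
#' @param n_ortho orthogonal components.
#' @param seed integer seed for the fold assignment.
#' @param folds optional pre-computed fold list (overrides `k`/`seed`).
#' @return numeric Q2 (at most 1; negative when the model predicts worse
#'   than the mean).
#' @export
cross_validated_q2 <- function(X, y, k = 7, n_ortho = 1, seed = 1L,
                               folds = NULL) {
  X <- as.matrix(X)
  n <- nrow(X)
  if (is.null(folds)) {
    check_flag(k >= 2 && k <= n, "k must lie in [2, n]; got k=%d, n=%d", k, n)
    folds <- make_folds(n, k, seed)
  }
  press <- 0
  for (fold in folds) {
    fit <- fit_opls(X[-fold, , drop = FALSE], y[-fold], n_ortho = n_ortho)
    pred <- predict(fit, X[fold, , drop = FALSE])
    press <- press + sum((y[fold] - pred)^2)
  }
  1 - press / sum((y - mean(y))^2)
}

#' Permutation p-value of Q2 (pQ2)
#'
#' Re-computes the cross-validated Q2 under `n_perm` random permutations
#' of the response and reports
#' pQ2 = (1 + #permuted Q2 >= observed) / (1 + n_perm). Fold assignment is
#' fixed across the permutation loop. Models with pQ2 above the rejection
#' threshold (0.05) are considered overfitted.
#'
#' @param X samples x features matrix.
#' @param y response vector.
#' @param n_perm number of response permutations (default 200; below 20 a
#'   warning flags the coarse resolution).
#' @param k folds.
#' @param n_ortho orthogonal components.
#' @param seed integer seed.
#' @return list with `Q2` (observed), `pQ2`, and `q2_perm` (the permuted
#'   Q2 values).
#' @export
permutation_pq2 <- function(X, y, n_perm = 200, k = 7, n_ortho = 1, seed = 1L) {
  if (n_perm < 20) warning("n_perm < 20: pQ2 resolution is very coarse")
  n <- length(y)
  folds <- make_folds(n, k, sub_seed(seed, 31L))
  q2_obs <- cross_validated_q2(X, y, n_ortho = n_ortho, folds = folds)
  perms <- with_seed(sub_seed(seed, 32L),
                     lapply(seq_len(n_perm), function(i) sample(n)))
  q2_perm <- vapply(perms, function(idx) {
    cross_validated_q2(X, y[idx], n_ortho = n_ortho, folds = folds)
  }, numeric(1))
  list(Q2 = q2_obs,
       pQ2 = perm_pvalue(sum(q2_perm >= q2_obs - 1e-12), n_perm),
       q2_perm = q2_perm)
}

#' Classify OPLS model quality
#'
#' A model is `rejected` (overfitted) when pQ2 exceeds `pq2_max`; `good`
#' when not rejected and both R2X > `r2x_min` and Q2 > `q2_min`;
#' otherwise `acceptable`.
#'
#' @param model an `opls_model` with `Q2` and `pQ2` set, or a list/row
#'   with elements `R2X`, `Q2`, `pQ2`.
#' @param r2x_min,q2_min,pq2_max quality gates (defaults 0.9, 0.5, 0.05).
#' @return one of `"rejected"`, `"acceptable"`, `"good"`.
#' @export
evaluate_model <- function(model, r2x_min = 0.9, q2_min = 0.5, pq2_max = 0.05) {
  r2x <- model$R2X; q2 <- model$Q2; pq2 <- model$pQ2
  check_flag(!is.null(q2) && !is.null(pq2),
             "model must carry Q2 and pQ2 (run cross_validated_q2 / permutation_pq2)")
  if (pq2 > pq2_max) return("rejected")
  if (r2x > r2x_min && q2 > q2_min) return("good")
  "acceptable"
}

#' Fit the full OPLS model battery
#'
#' One depth model per combination of experiment (feature table), species
#' (sample subset) and filtering variant — the study design of 4
#' experiments x 3 species x 3 filters = 36 models.
#'
#' @param tables named list of raw [metabo_table()]s, one per experiment.
#' @param metadata sample metadata with `sample_id`, `species`, `depth`.
#' @param filters filtering variants to apply (default all three).
#' @param n_ortho,k,n_perm OPLS settings.
#' @param pq2_max,r2x_min,q2_min quality gates.
#' @param seed integer seed.
#' @return data.frame with one row per model: `experiment`, `species`,
#'   `filter`, `n_samples`, `n_features`, `R2X`, `R2Y`, `Q2`, `pQ2`,
#'   `verdict`; VIP vectors in attribute `"vip"` (named list).
#' @export
opls_battery <- function(tables, metadata, filters = c("cleaned", "pc_group", "ion"),
                         n_ortho = 1, k = 7, n_perm = 99,
                         pq2_max = 0.05, r2x_min = 0.9, q2_min = 0.5,
                         seed = 1L) {
  species <- unique(metadata$species)
  rows <- list()
  vips <- list()
  job <- 0L
  for (exp_name in names(tables)) {
    for (filt in filters) {
      filtered <- apply_filter_variant(tables[[exp_name]], filt)$table
      for (sp in species) {
        job <- job + 1L
        samp <- metadata$sample_id[metadata$species == sp]
        cols <- intersect(colnames(sample_intensity(filtered)), samp)
        X <- t(sample_intensity(filtered)[, cols, drop = FALSE])
        X <- log1p(X)
        y <- metadata$depth[match(cols, metadata$sample_id)]
        fit <- fit_opls(X, y, n_ortho = n_ortho)
        pq <- permutation_pq2(X, y, n_perm = n_perm, k = min(k, nrow(X)),
                              n_ortho = n_ortho, seed = sub_seed(seed, 100L + job))
        fit$Q2 <- pq$Q2; fit$pQ2 <- pq$pQ2
        verdict <- evaluate_model(fit, r2x_min, q2_min, pq2_max)
        key <- paste(exp_name, sp, filt, sep = "|")
        vips[[key]] <- fit$vip
        rows[[key]] <- data.frame(
          experiment = exp_name, species = sp, filter = filt,
          n_samples = nrow(X), n_features = ncol(X),
          R2X = fit$R2X, R2Y = fit$R2Y, Q2 = pq$Q2, pQ2 = pq$pQ2,
          verdict = verdict, stringsAsFactors = FALSE
        )
      }
    }
  }
  out <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  attr(out, "vip") <- vips
  out
}
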