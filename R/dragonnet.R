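# Three-headed neural potential-outcome estimator (Dragonnet).
#
# A shared representation phi(X) feeds two outcome heads (predicted stroke
# probability under treatment and under control; each head two hidden
# layers) and a single linear propensity head with a sigmoid.  The loss is
# the factual arm-specific cross-entropy plus a weighted propensity
# cross-entropy plus an optional targeted-regularization term with a
# trainable scalar fluctuation parameter.  Training is plain minibatch Adam
# with early stopping on a validation split; forward, backward and the
# optimizer are implemented directly with matrix algebra, so results are
# exactly reproducible from the seed.

elu <- function(z) {
  neg <- z < 0
  z[neg] <- exp(z[neg]) - 1
  z
}
# derivative recovered from the activation: a + 1 on the negative branch
elu_grad_from_act <- function(a) {
  pos <- a > 0
  a[!pos] <- a[!pos] + 1
  a[pos] <- 1
  a
}
sigmoid <- function(z) 1 / (1 + exp(-z))
add_bias <- function(z, b) z + rep(b, each = nrow(z))

#' Configure a Dragonnet fit
#'
#' @param rep_width width of each shared representation layer (default 200).
#' @param rep_depth number of representation layers (default 3).
#' @param head_width width of the two hidden layers in each outcome head
#'   (default 100; head depth is fixed at 2).
#' @param alpha_loss weight of the propensity cross-entropy term in the
#'   joint loss (default 1).
#' @param targeted_reg strength of the targeted-regularization term
#'   (default 1; 0 disables it and freezes the fluctuation parameter).
#' @param epochs maximum training epochs.
#' @param batch_size minibatch size.
#' @param learning_rate Adam step size.
#' @param val_fraction fraction of rows held out for early stopping.
#' @param patience epochs without validation improvement before stopping.
#' @param seed seed fixing initialization, the split and batch order.
#' @param clip propensity clipping bounds used wherever the propensity
#'   enters as an inverse weight.
#' @return an object of class \code{dragonnet_config}.
#' @export
dragonnet_config <- function(rep_width = 200L, rep_depth = 3L,
                             head_width = 100L, alpha_loss = 1,
                             targeted_reg = 1, epochs = 30L,
                             batch_size = 512L, learning_rate = 1e-3,
                             val_fraction = 0.2, patience = 5L, seed = 1L,
                             clip = c(0.01, 0.99)) {
  stopifnot(rep_width >= 1L, rep_depth >= 1L, head_width >= 1L,
            alpha_loss >= 0, targeted_reg >= 0, epochs >= 1L)
  structure(list(rep_width = as.integer(rep_width),
                 rep_depth = as.integer(rep_depth),
                 head_width = as.integer(head_width),
                 head_depth = 2L,
                 alpha_loss = alpha_loss, targeted_reg = targeted_reg,
                 epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size),
                 learning_rate = learning_rate,
                 val_fraction = val_fraction, patience = as.integer(patience),
                 seed = as.integer(seed), clip = clip),
            class = "dragonnet_config")
}

dnet_init <- function(d, cfg) {
  he <- function(n_in, n_out)
    matrix(stats::rnorm(n_in * n_out, 0, sqrt(2 / n_in)), n_in, n_out)
  p <- list()
  widths <- c(d, rep(cfg$rep_width, cfg$rep_depth))
  for (l in seq_len(cfg$rep_depth)) {
    p[[paste0("rep_W", l)]] <- he(widths[l], widths[l + 1L])
    p[[paste0("rep_b", l)]] <- numeric(widths[l + 1L])
  }
  for (h in c("h1", "h0")) {
    p[[paste0(h, "_W1")]] <- he(cfg$rep_width, cfg$head_width)
    p[[paste0(h, "_b1")]] <- numeric(cfg$head_width)
    p[[paste0(h, "_W2")]] <- he(cfg$head_width, cfg$head_width)
    p[[paste0(h, "_b2")]] <- numeric(cfg$head_width)
    p[[paste0(h, "_W3")]] <- matrix(stats::rnorm(cfg$head_width, 0,
                                                 1 / sqrt(cfg$head_width)),
                                    cfg$head_width, 1L)
    p[[paste0(h, "_b3")]] <- 0
  }
  p$pr_W <- matrix(stats::rnorm(cfg$rep_width, 0, 1 / sqrt(cfg$rep_width)),
                   cfg$rep_width, 1L)
  p$pr_b <- 0
  p$eps <- 0
  p
}

dnet_forward <- function(p, X, cfg, cache = FALSE) {
  nr <- cfg$rep_depth
  rep_acts <- vector("list", nr + 1L)
  rep_acts[[1L]] <- X
  for (l in seq_len(nr))
    rep_acts[[l + 1L]] <- elu(add_bias(rep_acts[[l]] %*% p[[paste0("rep_W", l)]],
                                       p[[paste0("rep_b", l)]]))
  phi <- rep_acts[[nr + 1L]]
  head_fwd <- function(h) {
    a1 <- elu(add_bias(phi %*% p[[paste0(h, "_W1")]], p[[paste0(h, "_b1")]]))
    a2 <- elu(add_bias(a1 %*% p[[paste0(h, "_W2")]], p[[paste0(h, "_b2")]]))
    q <- as.numeric(a2 %*% p[[paste0(h, "_W3")]]) + p[[paste0(h, "_b3")]]
    list(a1 = a1, a2 = a2, q = q)
  }
  f1 <- head_fwd("h1"); f0 <- head_fwd("h0")
  glogit <- as.numeric(phi %*% p$pr_W) + p$pr_b
  out <- list(q1 = f1$q, q0 = f0$q, glogit = glogit)
  if (cache) out <- c(out, list(rep_acts = rep_acts, f1 = f1, f0 = f0))
  out
}

dnet_loss_parts <- function(p, fw, t, y, cfg) {
  p1 <- sigmoid(fw$q1); p0 <- sigmoid(fw$q0); g <- sigmoid(fw$glogit)
  epsm <- 1e-7
  bce <- function(lab, prob)
    -(lab * log(pmax(prob, epsm)) + (1 - lab) * log(pmax(1 - prob, epsm)))
  l_out <- mean(t * bce(y, p1) + (1 - t) * bce(y, p0))
  l_prop <- cfg$alpha_loss * mean(bce(t, g))
  gc <- pmin(pmax(g, cfg$clip[1L]), cfg$clip[2L])
  qf <- t * p1 + (1 - t) * p0
  hcc <- t / gc - (1 - t) / (1 - gc)
  ypert <- qf + p$eps * hcc
  l_treg <- cfg$targeted_reg * mean((y - ypert)^2)
  list(total = l_out + l_prop + l_treg, outcome = l_out,
       propensity = l_prop, treg = l_treg,
       p1 = p1, p0 = p0, g = g, gc = gc, hcc = hcc, ypert = ypert)
}

# gradients of the joint loss; the targeted-regularization term treats the
# clipped propensity as a fixed clever covariate (no gradient through g)
dnet_backward <- function(p, fw, parts, t, y, cfg) {
  n <- length(t)
  g <- list()
  dq1 <- t * (parts$p1 - y) / n
  dq0 <- (1 - t) * (parts$p0 - y) / n
  dg <- cfg$alpha_loss * (parts$g - t) / n
  if (cfg$targeted_reg > 0) {
    r <- 2 * cfg$targeted_reg * (parts$ypert - y) / n
    g$eps <- sum(r * parts$hcc)
    dq1 <- dq1 + r * t * parts$p1 * (1 - parts$p1)
    dq0 <- dq0 + r * (1 - t) * parts$p0 * (1 - parts$p0)
  } else {
    g$eps <- 0
  }
  phi <- fw$rep_acts[[cfg$rep_depth + 1L]]
  head_bwd <- function(h, f, dq) {
    dq <- matrix(dq, ncol = 1L)
    g[[paste0(h, "_W3")]] <<- crossprod(f$a2, dq)
    g[[paste0(h, "_b3")]] <<- sum(dq)
    da2 <- (dq %*% t(p[[paste0(h, "_W3")]])) * elu_grad_from_act(f$a2)
    g[[paste0(h, "_W2")]] <<- crossprod(f$a1, da2)
    g[[paste0(h, "_b2")]] <<- colSums(da2)
    da1 <- (da2 %*% t(p[[paste0(h, "_W2")]])) * elu_grad_from_act(f$a1)
    g[[paste0(h, "_W1")]] <<- crossprod(phi, da1)
    g[[paste0(h, "_b1")]] <<- colSums(da1)
    da1 %*% t(p[[paste0(h, "_W1")]])
  }
  dphi <- head_bwd("h1", fw$f1, dq1) + head_bwd("h0", fw$f0, dq0)
  dgm <- matrix(dg, ncol = 1L)
  g$pr_W <- crossprod(phi, dgm)
  g$pr_b <- sum(dgm)
  dphi <- dphi + dgm %*% t(p$pr_W)
  dh <- dphi
  for (l in rev(seq_len(cfg$rep_depth))) {
    a_out <- fw$rep_acts[[l + 1L]]
    dz <- dh * elu_grad_from_act(a_out)
    g[[paste0("rep_W", l)]] <- crossprod(fw$rep_acts[[l]], dz)
    g[[paste0("rep_b", l)]] <- colSums(dz)
    if (l > 1L) dh <- dz %*% t(p[[paste0("rep_W", l)]])
  }
  g
}

adam_step <- function(p, g, state, lr, b1 = 0.9, b2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  corr1 <- 1 - b1^state$t
  corr2 <- 1 - b2^state$t
  for (k in names(g)) {
    state$m[[k]] <- b1 * state$m[[k]] + (1 - b1) * g[[k]]
    state$v[[k]] <- b2 * state$v[[k]] + (1 - b2) * g[[k]]^2
    p[[k]] <- p[[k]] - lr * (state$m[[k]] / corr1) /
      (sqrt(state$v[[k]] / corr2) + eps)
  }
  list(p = p, state = state)
}

default_dragonnet_covariates <- function(cohort, exposure, outcome) {
  cols <- setdiff(names(cohort), c(exposure, outcome, "y_latent"))
  dag <- stroke_dag()
  if (exposure %in% dag$nodes)
    cols <- setdiff(cols, descendants(dag, exposure))
  cols
}

#' Fit a Dragonnet potential-outcome model
#'
#' Trains the three-headed network on a cohort: each observation
#' contributes to the outcome loss only through the head matching its
#' factual arm, the propensity head is trained on the observed exposure,
#' and (by default) a targeted-regularization term with a trainable scalar
#' fluctuation nudges the outcome heads toward an efficient average-effect
#' estimate.  Continuous covariates are z-scored with training-split
#' statistics; binary covariates enter raw.
#'
#' @param cohort cohort data frame.
#' @param exposure binary exposure column (default the antiplatelet
#'   treatment \code{"t"}).
#' @param covariates covariate columns; defaults to every column except the
#'   exposure, the outcomes and (for exposures on the stroke diagram) the
#'   exposure's descendants.
#' @param outcome binary outcome column (default \code{"y"}).
#' @param config a \code{\link{dragonnet_config}}.
#' @return an object of class \code{dragonnet}: weights, config,
#'   normalization constants, covariate schema and a per-epoch loss history
#'   (\code{history$train}, \code{history$val}).
#' @seealso \code{\link{predict_potential_outcomes}},
#'   \code{\link{dragonnet_ate}}, \code{\link{cate}},
#'   \code{\link{causal_risk_ratio}}
#' @export
fit_dragonnet <- function(cohort, exposure = "t", covariates = NULL,
                          outcome = "y", config = dragonnet_config()) {
  stopifnot(inherits(config, "dragonnet_config"))
  if (is.null(covariates))
    covariates <- default_dragonnet_covariates(cohort, exposure, outcome)
  t_all <- cohort[[exposure]]
  y_all <- cohort[[outcome]]
  check_binary(t_all, "exposure")
  X_raw <- as.matrix(cohort[, covariates, drop = FALSE])
  with_seed(config$seed, {
    n <- nrow(X_raw)
    n_val <- max(1L, round(config$val_fraction * n))
    idx <- sample.int(n)
    val_idx <- idx[seq_len(n_val)]
    tr_idx <- idx[-seq_len(n_val)]
    is_cont <- apply(X_raw[tr_idx, , drop = FALSE], 2L,
                     function(v) length(unique(v)) > 2L)
    center <- ifelse(is_cont, colMeans(X_raw[tr_idx, , drop = FALSE]), 0)
    scale_ <- ifelse(is_cont,
                     apply(X_raw[tr_idx, , drop = FALSE], 2L, stats::sd), 1)
    scale_[scale_ == 0 | is.na(scale_)] <- 1
    X <- sweep(sweep(X_raw, 2L, center), 2L, scale_, "/")
    p <- dnet_init(ncol(X), config)
    state <- list(t = 0L,
                  m = lapply(p, function(x) x * 0),
                  v = lapply(p, function(x) x * 0))
    Xtr <- X[tr_idx, , drop = FALSE]; ttr <- t_all[tr_idx]; ytr <- y_all[tr_idx]
    Xva <- X[val_idx, , drop = FALSE]; tva <- t_all[val_idx]; yva <- y_all[val_idx]
    ntr <- length(tr_idx)
    best <- list(loss = Inf, p = p, epoch = 0L)
    hist_tr <- hist_va <- numeric(0)
    wait <- 0L
    for (epoch in seq_len(config$epochs)) {
      ord <- sample.int(ntr)
      starts <- seq(1L, ntr, by = config$batch_size)
      for (s in starts) {
        rows <- ord[s:min(s + config$batch_size - 1L, ntr)]
        fw <- dnet_forward(p, Xtr[rows, , drop = FALSE], config, cache = TRUE)
        parts <- dnet_loss_parts(p, fw, ttr[rows], ytr[rows], config)
        if (!is.finite(parts$total))
          stop("non-finite training loss at epoch ", epoch,
               " (outcome loss ", signif(parts$outcome, 4), ", propensity ",
               signif(parts$propensity, 4), ")")
        grads <- dnet_backward(p, fw, parts, ttr[rows], ytr[rows], config)
        if (config$targeted_reg == 0) grads$eps <- 0
        upd <- adam_step(p, grads, state, config$learning_rate)
        p <- upd$p; state <- upd$state
      }
      l_tr <- dnet_loss_parts(p, dnet_forward(p, Xtr, config), ttr, ytr,
                              config)$total
      l_va <- dnet_loss_parts(p, dnet_forward(p, Xva, config), tva, yva,
                              config)$total
      hist_tr <- c(hist_tr, l_tr); hist_va <- c(hist_va, l_va)
      if (l_va < best$loss - 1e-6) {
        best <- list(loss = l_va, p = p, epoch = epoch)
        wait <- 0L
      } else {
        wait <- wait + 1L
        if (wait >= config$patience) break
      }
    }
    structure(list(params = best$p, config = config,
                   covariates = covariates, exposure = exposure,
                   outcome = outcome, center = center, scale = scale_,
                   history = list(train = hist_tr, val = hist_va,
                                  best_epoch = best$epoch,
                                  best_val_loss = best$loss)),
              class = "dragonnet")
  })
}

#' @export
print.dragonnet <- function(x, ...) {
  cfg <- x$config
  cat(sprintf(
    "dragonnet: %d-wide x%d representation, %d-wide x2 heads | %d covariates\n",
    cfg$rep_width, cfg$rep_depth, cfg$head_width, length(x$covariates)))
  cat(sprintf("  trained %d epochs (best %d, val loss %.4f)\n",
              length(x$history$train), x$history$best_epoch,
              x$history$best_val_loss))
  invisible(x)
}

#' Predict potential outcomes and propensity
#'
#' Deterministic forward pass through a fitted Dragonnet, using the
#' normalization constants stored at training time.
#'
#' @param model a fitted \code{dragonnet}.
#' @param cohort data frame containing the model's covariate columns.
#' @return an object of class \code{dragonnet_predictions}: data frame with
#'   \code{y1_hat}, \code{y0_hat}, \code{e_hat}, all in (0, 1).
#' @export
predict_potential_outcomes <- function(model, cohort) {
  stopifnot(inherits(model, "dragonnet"))
  missing <- setdiff(model$covariates, names(cohort))
  if (length(missing))
    stop("cohort lacks covariate column(s): ", paste(missing, collapse = ", "))
  X <- as.matrix(cohort[, model$covariates, drop = FALSE])
  X <- sweep(sweep(X, 2L, model$center), 2L, model$scale, "/")
  fw <- dnet_forward(model$params, X, model$config)
  out <- data.frame(y1_hat = sigmoid(fw$q1), y0_hat = sigmoid(fw$q0),
                    e_hat = sigmoid(fw$glogit))
  class(out) <- c("dragonnet_predictions", "data.frame")
  out
}

#' @export
predict.dragonnet <- function(object, newdata, ...) {
  predict_potential_outcomes(object, newdata)
}

#' Average treatment effect from Dragonnet predictions
#'
#' \code{method = "plugin"} averages \code{y1_hat - y0_hat};
#' \code{method = "aipw"} applies the doubly robust correction using the
#' network's own clipped propensity head and the observed factual outcomes,
#' with an influence-function standard error (the recommended estimator:
#' the targeted-regularization loss shapes the heads for exactly this
#' correction).
#'
#' @param preds a \code{dragonnet_predictions} object.
#' @param cohort the cohort (needed for \code{"aipw"}).
#' @param exposure,outcome column names in \code{cohort}.
#' @param method \code{"aipw"} (default) or \code{"plugin"}.
#' @param clip propensity clipping bounds.
#' @return an \code{\link{effect_estimate}} (risk difference).
#' @export
dragonnet_ate <- function(preds, cohort = NULL, exposure = "t",
                          outcome = "y", method = c("aipw", "plugin"),
                          clip = c(0.01, 0.99)) {
  method <- match.arg(method)
  if (method == "plugin")
    return(effect_estimate("dragonnet-plugin", exposure,
                           mean(preds$y1_hat - preds$y0_hat)))
  stopifnot(!is.null(cohort))
  a <- cohort[[exposure]]; y <- cohort[[outcome]]
  e <- pmin(pmax(preds$e_hat, clip[1L]), clip[2L])
  psi <- preds$y1_hat - preds$y0_hat +
    a * (y - preds$y1_hat) / e - (1 - a) * (y - preds$y0_hat) / (1 - e)
  effect_estimate("dragonnet", exposure, mean(psi),
                  stats::sd(psi) / sqrt(length(psi)))
}

#' Conditional average treatment effects by stratum
#'
#' Averages \code{y1_hat - y0_hat} within each level combination of the
#' conditioning columns; an empty conditioning set returns the single
#' overall row.  Level combinations absent from the cohort are omitted with
#' a warning.
#'
#' @param preds a \code{dragonnet_predictions} object.
#' @param cohort the cohort the predictions refer to.
#' @param conditioning character vector of stratifying columns (possibly
#'   empty).
#' @return data frame with the conditioning columns, \code{n} and
#'   \code{cate}.
#' @export
cate <- function(preds, cohort, conditioning = character(0)) {
  ite_hat <- preds$y1_hat - preds$y0_hat
  if (!length(conditioning))
    return(data.frame(n = length(ite_hat), cate = mean(ite_hat)))
  stopifnot(all(conditioning %in% names(cohort)))
  key <- interaction(cohort[, conditioning, drop = FALSE], drop = FALSE)
  if (anyNA(match(levels(key), unique(key))))
    warning("empty stratum level(s) omitted from the CATE table")
  agg <- stats::aggregate(ite_hat, by = cohort[, conditioning, drop = FALSE],
                          FUN = mean)
  cnt <- stats::aggregate(ite_hat, by = cohort[, conditioning, drop = FALSE],
                          FUN = length)
  out <- agg
  names(out)[ncol(out)] <- "cate"
  out$n <- cnt[[ncol(cnt)]]
  out[, c(conditioning, "n", "cate")]
}

#' Causal risk ratio from Dragonnet predictions
#'
#' \code{mean(y1_hat) / mean(y0_hat)} with a patient-level percentile
#' bootstrap interval.
#'
#' @param preds a \code{dragonnet_predictions} object.
#' @param B bootstrap resamples.
#' @param seed RNG seed.
#' @return an \code{\link{effect_estimate}} on the risk-ratio scale.
#' @export
causal_risk_ratio <- function(preds, B = 200L, seed = 1L) {
  if (mean(preds$y0_hat) < 1e-8)
    stop("mean control risk is numerically zero; ratio undefined")
  rr <- mean(preds$y1_hat) / mean(preds$y0_hat)
  cis <- with_seed(seed, {
    n <- nrow(preds)
    reps <- vapply(seq_len(B), function(b) {
      i <- sample.int(n, n, replace = TRUE)
      mean(preds$y1_hat[i]) / mean(preds$y0_hat[i])
    }, numeric(1))
    stats::quantile(reps, c(0.025, 0.975), names = FALSE)
  })
  effect_estimate("dragonnet", "t", rr, ci_low = cis[1L], ci_high = cis[2L],
                  scale = "risk-ratio")
}
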