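# Manual reverse-mode gradients for the one-hidden-layer VAE. The forward
# pass mirrors encodeSequences()/decodeLatent(); gradients are derived from
# the categorical NLL + closed-form KL objective with the reparameterization
# trick (one sample per sequence per step).

.vaeStepGrads <- function(params, x, tg, klWeight) {
  n <- nrow(x)
  xin <- if (is.null(tg)) x else cbind(x, tg)
  h <- tanh(sweep(xin %*% params$W1, 2L, params$b1, "+"))
  mu <- sweep(h %*% params$Wmu, 2L, params$bmu, "+")
  lv <- sweep(h %*% params$Wlv, 2L, params$blv, "+")
  sd_ <- exp(lv / 2)
  eps <- matrix(stats::rnorm(length(mu)), n, ncol(mu))
  z <- mu + sd_ * eps
  zin <- if (is.null(tg)) z else cbind(z, tg)
  hd <- tanh(sweep(zin %*% params$W4, 2L, params$b4, "+"))
  logits <- sweep(hd %*% params$W5, 2L, params$b5, "+")
  P <- .columnSoftmax(logits, ncol(x) / 21L)

  rec <- -mean(rowSums(x * log(pmax(P, 1e-12))))
  kl <- mean(0.5 * rowSums(mu^2 + exp(lv) - lv - 1))

  dlogits <- (P - x) / n
  gW5 <- crossprod(hd, dlogits)
  gb5 <- colSums(dlogits)
  dhd <- (dlogits %*% t(params$W5)) * (1 - hd^2)
  gW4 <- crossprod(zin, dhd)
  gb4 <- colSums(dhd)
  dzin <- dhd %*% t(params$W4)
  dz <- dzin[, seq_len(ncol(mu)), drop = FALSE]

  dmu <- dz + klWeight * mu / n
  dlv <- dz * eps * sd_ * 0.5 + klWeight * 0.5 * (exp(lv) - 1) / n
  gWmu <- crossprod(h, dmu); gbmu <- colSums(dmu)
  gWlv <- crossprod(h, dlv); gblv <- colSums(dlv)
  dh <- (dmu %*% t(params$Wmu) + dlv %*% t(params$Wlv)) * (1 - h^2)
  gW1 <- crossprod(xin, dh)
  gb1 <- colSums(dh)

  list(grads = list(W1 = gW1, b1 = gb1, Wmu = gWmu, bmu = gbmu,
                    Wlv = gWlv, blv = gblv, W4 = gW4, b4 = gb4,
                    W5 = gW5, b5 = gb5),
       reconstruction = rec, kl = kl,
       total = rec + klWeight * kl)
}

#' Train a SequenceVAE
#'
#' Minibatch Adam (learning rate 0.001 by default) on the reconstruction +
#' KL objective, with early stopping once the mean epoch training loss has
#' not improved on the best value seen for more than \code{patience}
#' consecutive epochs. Weight decay is either absent or follows the
#' decreasing schedule in [trainConfig()]. Fully seeded: initialization comes
#' from the model config seed, and shuffling plus reparameterization draws
#' from \code{seed}, so repeated runs are bit-identical on one platform
#' (single-threaded BLAS assumed for strict bitwise equality).
#'
#' @param model an untrained (or trained) [SequenceVAE-class].
#' @param x training one-hot input (matrix, 3-d array, character sequences,
#'   or a [ProteinMSA-class]).
#' @param tags 0-based solubility tag indices for conditional models.
#' @param config a [trainConfig()].
#' @param seed integer seed for shuffling and sampling (default: model seed).
#' @param verbose print the epoch loss every 25 epochs.
#' @return the trained [SequenceVAE-class] with \code{lossHistory} filled.
#' @export
trainVAE <- function(model, x, tags = NULL, config = trainConfig(),
                     seed = NULL, verbose = FALSE) {
  stopifnot(inherits(config, "trainConfig"))
  if (is(x, "ProteinMSA")) x <- sequences(x)
  x <- .asInputMatrix(model, x)
  n <- nrow(x)
  if (n < 1L) stop("empty training set")
  tg <- .tagOneHot(tags, n, model@config$conditionArity)
  if (is.null(seed)) seed <- model@config$seed
  set.seed(as.integer(seed))

  params <- model@params
  mom <- lapply(params, function(p) p * 0)
  vel <- mom
  b1 <- 0.9; b2 <- 0.999; epsA <- 1e-8
  t <- 0L
  best <- Inf; badStreak <- 0L
  hist <- matrix(NA_real_, config$maxEpochs, 3L,
                 dimnames = list(NULL, c("reconstruction", "kl", "total")))
  wd0 <- if (identical(config$weightDecay, "none")) 0 else
    config$weightDecay$initial
  wdf <- if (identical(config$weightDecay, "none")) 1 else
    config$weightDecay$factor

  for (epoch in seq_len(config$maxEpochs)) {
    ord <- sample.int(n)
    wd <- wd0 * wdf^(epoch - 1L)
    starts <- seq(1L, n, by = config$batchSize)
    accRec <- 0; accKl <- 0
    for (s in starts) {
      idx <- ord[s:min(s + config$batchSize - 1L, n)]
      st <- .vaeStepGrads(params, x[idx, , drop = FALSE],
                          if (is.null(tg)) NULL else tg[idx, , drop = FALSE],
                          model@config$klWeight)
      if (!is.finite(st$total))
        stop("training diverged: non-finite loss at epoch ", epoch)
      t <- t + 1L
      for (nm in names(params)) {
        g <- st$grads[[nm]]
        if (wd > 0 && is.matrix(params[[nm]])) g <- g + wd * params[[nm]]
        mom[[nm]] <- b1 * mom[[nm]] + (1 - b1) * g
        vel[[nm]] <- b2 * vel[[nm]] + (1 - b2) * g^2
        mhat <- mom[[nm]] / (1 - b1^t)
        vhat <- vel[[nm]] / (1 - b2^t)
        params[[nm]] <- params[[nm]] -
          config$learningRate * mhat / (sqrt(vhat) + epsA)
      }
      w <- length(idx) / n
      accRec <- accRec + w * st$reconstruction
      accKl <- accKl + w * st$kl
    }
    tot <- accRec + model@config$klWeight * accKl
    hist[epoch, ] <- c(accRec, accKl, tot)
    if (verbose && epoch %% 25L == 0L)
      message(sprintf("epoch %d: rec %.3f kl %.3f total %.3f",
                      epoch, accRec, accKl, tot))
    if (tot < best - 1e-6) {
      best <- tot
      badStreak <- 0L
    } else {
      badStreak <- badStreak + 1L
      if (badStreak > config$patience) break
    }
  }
  model@params <- params
  model@trained <- TRUE
  model@lossHistory <- hist[!is.na(hist[, 1L]), , drop = FALSE]
  model
}

#' Apply the early-stopping rule to a loss sequence
#'
#' Returns the 1-based index of the epoch after which training stops (the
#' epoch at which the count of consecutive epochs without improvement on the
#' running best first exceeds \code{patience}), or \code{length(losses)} if
#' the rule never fires. Improvement means beating the best seen so far by
#' more than \code{tol}.
#'
#' @param losses numeric vector of per-epoch losses.
#' @param patience tolerated consecutive non-improving epochs (default 3).
#' @param tol absolute improvement tolerance (default 1e-6).
#' @return integer stopping epoch.
#' @export
earlyStopEpoch <- function(losses, patience = 3L, tol = 1e-6) {
  best <- Inf; bad <- 0L
  for (i in seq_along(losses)) {
    if (losses[i] < best - tol) {
      best <- losses[i]; bad <- 0L
    } else {
      bad <- bad + 1L
      if (bad > patience) return(i)
    }
  }
  length(losses)
}

#' Save / load a model checkpoint
#'
#' Self-describing versioned JSON: config, the flat parameter vectors with
#' their shapes, the fixed symbol order, and an optional column map, so a
#' checkpoint decodes identically anywhere.
#'
#' @param model a [SequenceVAE-class].
#' @param path checkpoint file (JSON).
#' @param columnMap optional 0-based kept-column indices to embed.
#' @export
saveCheckpoint <- function(model, path, columnMap = NULL) {
  obj <- list(
    format = "SeqVAE-checkpoint", version = 1L,
    config = model@config,
    trained = model@trained,
    symbols = AA_ALPHABET,
    columnMap = columnMap,
    lossHistory = model@lossHistory,
    shapes = lapply(model@params, function(p)
      if (is.matrix(p)) dim(p) else length(p)),
    params = lapply(model@params, as.vector))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname saveCheckpoint
#' @return \code{readCheckpoint}: list with elements \code{model} and
#'   \code{columnMap}.
#' @export
readCheckpoint <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(obj$format, "SeqVAE-checkpoint"))
    stop(path, " is not a SeqVAE checkpoint")
  if (!identical(unname(unlist(obj$symbols)), AA_ALPHABET))
    stop("checkpoint symbol order differs from this build")
  cf <- obj$config
  config <- modelConfig(msaWidth = cf$msaWidth, hiddenWidth = cf$hiddenWidth,
                        latentDim = cf$latentDim,
                        conditionArity = cf$conditionArity,
                        klWeight = cf$klWeight, seed = cf$seed)
  params <- lapply(names(obj$params), function(nm) {
    v <- obj$params[[nm]]
    sh <- obj$shapes[[nm]]
    if (length(sh) == 2L) matrix(v, sh[1L], sh[2L]) else as.numeric(v)
  })
  names(params) <- names(obj$params)
  lh <- obj$lossHistory
  if (is.null(lh) || length(lh) == 0L)
    lh <- matrix(numeric(0), ncol = 3L)
  lh <- matrix(as.numeric(lh), ncol = 3L,
               dimnames = list(NULL, c("reconstruction", "kl", "total")))
  model <- new("SequenceVAE", config = unclass(config), params = params,
               trained = isTRUE(obj$trained), lossHistory = lh)
  list(model = model, columnMap = if (is.null(obj$columnMap)) NULL
       else as.integer(obj$columnMap))
}
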