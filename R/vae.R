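#' Model architecture configuration
#'
#' The architecture is deliberately small: one tanh hidden layer of
#' \code{hiddenWidth} neurons in both the encoder and the decoder (default:
#' the MSA width N), a 2-dimensional latent space, no dropout, and equal
#' weighting of the reconstruction and KL regularization terms. A conditional
#' model (\code{conditionArity = 3}) appends a one-hot solubility tag
#' (LOW/MEDIUM/HIGH) to both the encoder input and the decoder input.
#'
#' @param msaWidth number of alignment columns N.
#' @param alphabetSize fixed at 21 (20 amino acids + gap).
#' @param hiddenWidth hidden layer size; defaults to \code{msaWidth}.
#' @param latentDim latent dimensionality (default 2).
#' @param activation hidden nonlinearity; only \code{"tanh"} is supported.
#' @param conditionArity 0 for a plain VAE, 3 for the tagged CVAE.
#' @param klWeight weight of the KL term in the loss (default 1: equal
#'   weighting with the reconstruction term).
#' @param seed integer seed controlling parameter initialization.
#' @return a list of class \code{"modelConfig"}.
#' @export
modelConfig <- function(msaWidth, alphabetSize = 21L, hiddenWidth = msaWidth,
                        latentDim = 2L, activation = "tanh",
                        conditionArity = 0L, klWeight = 1, seed = 1L) {
  stopifnot(msaWidth >= 1L, latentDim >= 1L, hiddenWidth >= 1L,
            alphabetSize == 21L, klWeight >= 0)
  if (!identical(activation, "tanh"))
    stop("only the tanh activation is supported")
  if (!conditionArity %in% c(0L, 3L))
    stop("conditionArity must be 0 (plain VAE) or 3 (solubility tags)")
  structure(list(msaWidth = as.integer(msaWidth), alphabetSize = 21L,
                 hiddenWidth = as.integer(hiddenWidth),
                 latentDim = as.integer(latentDim), activation = "tanh",
                 conditionArity = as.integer(conditionArity),
                 klWeight = klWeight, seed = as.integer(seed)),
            class = "modelConfig")
}

#' Training protocol configuration
#'
#' Adam with learning rate 0.001, early stopping once the epoch training
#' loss has failed to improve on the best value seen for more than
#' \code{patience} consecutive epochs (absolute tolerance 1e-6), and either
#' no weight decay or an exponentially decreasing per-epoch weight decay.
#'
#' @param learningRate Adam step size (default 0.001).
#' @param patience consecutive non-improving epochs tolerated (default 3).
#' @param maxEpochs hard epoch cap (default 1000).
#' @param batchSize minibatch size (default 128).
#' @param weightDecay either \code{"none"} or
#'   \code{list(initial =, factor =)} for the decreasing schedule
#'   \eqn{w_t = initial \cdot factor^t}.
#' @return a list of class \code{"trainConfig"}.
#' @export
trainConfig <- function(learningRate = 0.001, patience = 3L,
                        maxEpochs = 1000L, batchSize = 128L,
                        weightDecay = "none") {
  stopifnot(learningRate > 0, patience >= 1L, maxEpochs >= 1L, batchSize >= 1L)
  if (!identical(weightDecay, "none")) {
    stopifnot(is.list(weightDecay),
              all(c("initial", "factor") %in% names(weightDecay)),
              weightDecay$initial >= 0, weightDecay$factor > 0,
              weightDecay$factor <= 1)
  }
  structure(list(learningRate = learningRate, patience = as.integer(patience),
                 maxEpochs = as.integer(maxEpochs),
                 batchSize = as.integer(batchSize),
                 weightDecay = weightDecay),
            class = "trainConfig")
}

.glorot <- function(nin, nout) {
  r <- sqrt(6 / (nin + nout))
  matrix(stats::runif(nin * nout, -r, r), nin, nout)
}

#' Initialize a SequenceVAE
#'
#' Glorot-uniform weights, zero biases, reproducible from
#' \code{config$seed}.
#'
#' @param config a [modelConfig()].
#' @return an untrained [SequenceVAE-class].
#' @export
initModel <- function(config) {
  stopifnot(inherits(config, "modelConfig"))
  D <- config$msaWidth * 21L + config$conditionArity
  H <- config$hiddenWidth
  L <- config$latentDim
  Dout <- config$msaWidth * 21L
  set.seed(config$seed)
  params <- list(
    W1 = .glorot(D, H),            b1 = numeric(H),
    Wmu = .glorot(H, L),           bmu = numeric(L),
    Wlv = .glorot(H, L),           blv = numeric(L),
    W4 = .glorot(L + config$conditionArity, H), b4 = numeric(H),
    W5 = .glorot(H, Dout),         b5 = numeric(Dout))
  new("SequenceVAE", config = unclass(config), params = params,
      trained = FALSE,
      lossHistory = matrix(numeric(0), ncol = 3L,
                           dimnames = list(NULL,
                                           c("reconstruction", "kl", "total"))))
}

#' @keywords internal
.tagOneHot <- function(tags, n, arity) {
  if (arity == 0L) {
    if (!is.null(tags)) stop("this model is unconditional: tags are rejected")
    return(NULL)
  }
  if (is.null(tags)) stop("conditional model requires a tag per sequence")
  tags <- as.integer(tags)
  if (length(tags) == 1L) tags <- rep(tags, n)
  if (length(tags) != n) stop("need one tag per sequence")
  if (any(tags < 0L | tags >= arity)) stop("tag indices must be in 0..", arity - 1L)
  t1 <- matrix(0, n, arity)
  t1[cbind(seq_len(n), tags + 1L)] <- 1
  t1
}

#' Encode sequences into latent Gaussians
#'
#' Deterministic given the parameters: returns the per-sequence posterior
#' mean and log-variance of the latent Gaussian.
#'
#' @param model a [SequenceVAE-class].
#' @param x one-hot input: a matrix \code{n x (width*21)} (see
#'   [encodeOneHot()] / the internal flattened layout), a 3-d one-hot array,
#'   or a character vector of aligned sequences.
#' @param tags integer tag indices (0-based) for conditional models; must be
#'   absent for unconditional models.
#' @return list with matrices \code{mean} and \code{logVar}, each
#'   \code{n x latentDim}.
#' @export
encodeSequences <- function(model, x, tags = NULL) {
  x <- .asInputMatrix(model, x)
  n <- nrow(x)
  tg <- .tagOneHot(tags, n, model@config$conditionArity)
  if (!is.null(tg)) x <- cbind(x, tg)
  if (ncol(x) != nrow(model@params$W1))
    stop("input width does not match the model (got ", ncol(x),
         ", expected ", nrow(model@params$W1), ")")
  p <- model@params
  h <- tanh(sweep(x %*% p$W1, 2L, p$b1, "+"))
  list(mean = sweep(h %*% p$Wmu, 2L, p$bmu, "+"),
       logVar = sweep(h %*% p$Wlv, 2L, p$blv, "+"))
}

.asInputMatrix <- function(model, x) {
  if (is.character(x)) x <- .seqsToX(x)
  if (length(dim(x)) == 3L) x <- .flattenOneHot(x)
  if (is.null(dim(x))) x <- matrix(x, nrow = 1L)
  W <- model@config$msaWidth * 21L
  if (ncol(x) != W)
    stop("one-hot width ", ncol(x), " does not match model width ", W)
  x
}

#' Draw reparameterized samples from latent Gaussians
#'
#' \code{mean + exp(logVar/2) * eps} with \code{eps} standard normal.
#'
#' @param gauss list with \code{mean} and \code{logVar} matrices (a single
#'   Gaussian may be given as vectors).
#' @param n number of draws per Gaussian (default 1).
#' @param seed optional integer seed.
#' @return matrix of latent points; for \code{n > 1} the draws for each row
#'   are stacked (row-major: all draws of Gaussian 1, then 2, ...).
#' @export
sampleLatent <- function(gauss, n = 1L, seed = NULL) {
  mu <- rbind(gauss$mean); lv <- rbind(gauss$logVar)
  if (!is.null(seed)) set.seed(as.integer(seed))
  k <- nrow(mu)
  mu <- mu[rep(seq_len(k), each = n), , drop = FALSE]
  lv <- lv[rep(seq_len(k), each = n), , drop = FALSE]
  eps <- matrix(stats::rnorm(length(mu)), nrow(mu), ncol(mu))
  mu + exp(lv / 2) * eps
}

#' Stable per-column softmax over the flattened logits layout
#' @keywords internal
.columnSoftmax <- function(logits, width) {
  n <- nrow(logits)
  a <- matrix(t(logits), nrow = 21L)           # 21 x (width*n)
  mx <- a[1L, ]
  for (s in 2:21) mx <- pmax(mx, a[s, ])
  e <- exp(sweep(a, 2L, mx, "-"))
  e <- sweep(e, 2L, .colSums(e, 21L, ncol(e)), "/")
  matrix(as.vector(e), nrow = n, byrow = TRUE)
}

#' Decode latent points into per-column residue distributions
#'
#' Each decoded point yields one categorical distribution over the 21
#' symbols per alignment column (per-column softmax), valid for arbitrary
#' finite latent points, including far outside the training cloud.
#'
#' @param model a [SequenceVAE-class].
#' @param z matrix \code{n x latentDim} (or a single vector) of latent
#'   points.
#' @param tags 0-based tag indices for conditional models.
#' @return matrix \code{n x (width*21)} of probabilities; each block of 21
#'   consecutive entries sums to 1.
#' @export
decodeLatent <- function(model, z, tags = NULL) {
  if (is.null(dim(z))) z <- matrix(z, nrow = 1L)
  if (ncol(z) != model@config$latentDim)
    stop("latent point length ", ncol(z), " does not match latentDim ",
         model@config$latentDim)
  tg <- .tagOneHot(tags, nrow(z), model@config$conditionArity)
  if (!is.null(tg)) z <- cbind(z, tg)
  p <- model@params
  h <- tanh(sweep(z %*% p$W4, 2L, p$b4, "+"))
  logits <- sweep(h %*% p$W5, 2L, p$b5, "+")
  .columnSoftmax(logits, model@config$msaWidth)
}

#' Argmax-decode latent points into aligned sequences
#'
#' Ties broken toward the lowest symbol index (fixed symbol order), so
#' decisions are platform-stable.
#'
#' @inheritParams decodeLatent
#' @return character vector of aligned sequences of the model's width.
#' @export
decodeToSequences <- function(model, z, tags = NULL) {
  probs <- decodeLatent(model, z, tags)
  .probsToSeqs(probs, model@config$msaWidth)
}

.probsToSeqs <- function(probs, width, sample = FALSE) {
  n <- nrow(probs)
  # 21 x (width*n); column c = (sequence i, alignment column j), j fastest
  a <- matrix(t(probs), nrow = 21L)
  M <- ncol(a)
  if (!sample) {
    idx <- max.col(t(a), ties.method = "first")
  } else {
    for (s in 2:21) a[s, ] <- a[s, ] + a[s - 1L, ]   # in-place cumsum
    u <- stats::runif(M)
    idx <- pmin(22L - .colSums(a > rep(u, each = 21L), 21L, M), 21L)
  }
  intsToSeq(t(matrix(idx, width, n)))
}

#' Closed-form KL divergence to the standard-normal prior
#'
#' \eqn{0.5 \sum_d (\mu_d^2 + \sigma_d^2 - \log \sigma_d^2 - 1)}; zero iff
#' the posterior equals the prior.
#'
#' @param gauss list with \code{mean} and \code{logVar} (vectors for one
#'   Gaussian or matrices for a batch).
#' @return nonnegative numeric vector, one KL per Gaussian.
#' @export
klTerm <- function(gauss) {
  mu <- rbind(gauss$mean); lv <- rbind(gauss$logVar)
  as.vector(0.5 * rowSums(mu^2 + exp(lv) - lv - 1))
}

#' Evaluate the VAE loss on a batch
#'
#' Reconstruction is the mean over sequences of the categorical negative
#' log-likelihood of the true symbols under one reparameterized
#' decode; the total adds \code{klWeight} times the mean closed-form KL.
#'
#' @param model a [SequenceVAE-class].
#' @param x one-hot batch (matrix, array, or sequences).
#' @param tags 0-based tags for conditional models.
#' @param seed seed for the reparameterization draw.
#' @return list \code{(reconstruction, kl, total)}.
#' @export
vaeLoss <- function(model, x, tags = NULL, seed = 1L) {
  x <- .asInputMatrix(model, x)
  g <- encodeSequences(model, x, tags)
  z <- sampleLatent(g, seed = seed)
  probs <- decodeLatent(model, z, tags)
  rec <- -mean(rowSums(x * log(pmax(probs, 1e-12))))
  kl <- mean(klTerm(g))
  list(reconstruction = rec, kl = kl,
       total = rec + model@config$klWeight * kl)
}
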