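# Cell cycle conv-net architectures.
#
# 3D network: four double-unit encoder blocks; each unit is
# [group normalization -> 3x3x3 convolution (stride 1, pad 1, no bias) ->
# ReLU], with 2x2x2 max pooling between blocks and a head of global
# max-pool -> dropout(0.5) -> affine 256 -> 1. Channel table:
# B1 1->16->32, B2 32->32->64, B3 64->64->128, B4 128->128->256
# (the first unit of a block halves the block's output width unless that
# would shrink below the input width). Normalization uses 8 channel
# groups, or 1 group when the unit input has fewer than 8 channels.
# Total: 1,757,267 trainable parameters.
#
# 2D variant: four single-unit blocks 1->32->64->128->256; the unit is
# [group norm -> 3x3 convolution (stride 1, pad 1, WITH bias) -> ReLU],
# 2x2 max pooling between blocks, identical head.
# Total: 388,547 trainable parameters.

.arch3dBlocks <- function()
  list(c(1L, 16L, 32L), c(32L, 32L, 64L), c(64L, 64L, 128L),
       c(128L, 128L, 256L))

.arch2dBlocks <- function()
  list(c(1L, 32L), c(32L, 64L), c(64L, 128L), c(128L, 256L))

.gnGroups <- function(ch) if (ch < 8L) 1L else 8L

# flat, ordered layer descriptors; params are named by block/unit
.buildLayers <- function(arch) {
  layers <- list()
  blocks <- if (arch == "3d") .arch3dBlocks() else .arch2dBlocks()
  K <- if (arch == "3d") 27L else 9L
  bias <- arch == "2d"
  for (b in seq_along(blocks)) {
    ch <- blocks[[b]]
    for (u in seq_len(length(ch) - 1L)) {
      cin <- ch[u]; cout <- ch[u + 1L]
      tag <- sprintf("b%du%d", b, u)
      layers <- c(layers, list(
        list(type = "gn", tag = tag, ch = cin, groups = .gnGroups(cin)),
        list(type = "conv", tag = tag, cin = cin, cout = cout, K = K,
             bias = bias),
        list(type = "relu")))
    }
    if (b < length(blocks)) layers <- c(layers, list(list(type = "pool")))
  }
  c(layers, list(list(type = "gmax"), list(type = "dropout", p = 0.5),
                 list(type = "linear", cin = 256L, cout = 1L)))
}

.initParams <- function(layers, seed) {
  set.seed(seed)
  params <- list()
  for (ly in layers) {
    if (ly$type == "gn") {
      params[[paste0(ly$tag, "_gn_gamma")]] <- rep(1, ly$ch)
      params[[paste0(ly$tag, "_gn_beta")]] <- rep(0, ly$ch)
    } else if (ly$type == "conv") {
      fan <- ly$cin * ly$K
      bd <- 1 / sqrt(fan)
      params[[paste0(ly$tag, "_conv_w")]] <-
        matrix(runif(ly$K * ly$cin * ly$cout, -bd, bd), ly$K * ly$cin,
               ly$cout)
      if (ly$bias)
        params[[paste0(ly$tag, "_conv_b")]] <- runif(ly$cout, -bd, bd)
    } else if (ly$type == "linear") {
      bd <- 1 / sqrt(ly$cin)
      params[["head_w"]] <- matrix(runif(ly$cin * ly$cout, -bd, bd),
                                   ly$cin, ly$cout)
      params[["head_b"]] <- runif(ly$cout, -bd, bd)
    }
  }
  params
}

#' Build the volumetric cell cycle network
#'
#' `buildCnn3d()` instantiates the 3D architecture (1,757,267 trainable
#' parameters); `buildCnn2d()` the 2D variant (388,547). The classification
#' head reads the output scalar as a logit (sigmoid gives the S/G2
#' probability); the regression head reads it as the cell cycle angle in
#' degrees. Both heads share every parameter shape.
#'
#' Weights are initialized with the standard fan-in uniform scheme,
#' deterministically from \code{initSeed}; normalization scale/offset start
#' at 1/0.
#'
#' @param mode \code{"classification"} or \code{"regression"}.
#' @param initSeed integer initialization seed.
#' @return A [CycleNet-class].
#' @examples
#' net <- buildCnn3d()
#' countParameters(net)
#' @export
buildCnn3d <- function(mode = c("classification", "regression"),
                       initSeed = 1L) {
  mode <- match.arg(mode)
  layers <- .buildLayers("3d")
  new("CycleNet", arch = "3d", mode = mode, layers = layers,
      params = .initParams(layers, initSeed), initSeed = as.integer(initSeed))
}

#' @rdname buildCnn3d
#' @export
buildCnn2d <- function(mode = c("classification", "regression"),
                       initSeed = 1L) {
  mode <- match.arg(mode)
  layers <- .buildLayers("2d")
  new("CycleNet", arch = "2d", mode = mode, layers = layers,
      params = .initParams(layers, initSeed), initSeed = as.integer(initSeed))
}

#' Count trainable parameters
#'
#' Sum of the sizes of every trainable tensor (normalization scales and
#' offsets, convolution kernels and biases, head weights and bias).
#'
#' @param net a [CycleNet-class].
#' @return integer total.
#' @export
countParameters <- function(net) {
  sum(vapply(net@params, length, integer(1)))
}

#' Per-part parameter subtotals
#'
#' @param net a [CycleNet-class].
#' @return data.frame \code{part} (b1..b4, head), \code{n_params}.
#' @export
paramCountTable <- function(net) {
  nm <- names(net@params)
  part <- ifelse(grepl("^head", nm), "head", substr(nm, 1, 2))
  agg <- tapply(vapply(net@params, length, integer(1)), part, sum)
  ord <- c(paste0("b", 1:4), "head")
  data.frame(part = ord, n_params = as.integer(agg[ord]),
             row.names = NULL)
}

#' Load encoder weights from an external checkpoint by name mapping
#'
#' Replaces any parameter whose name appears in \code{weights} with the
#' supplied array (shapes must match). This is the hook for initializing
#' the encoder from externally trained weights; names not supplied are
#' left at their current values.
#'
#' @param net a [CycleNet-class].
#' @param weights named list of arrays (a subset of \code{names(netParams(net))}).
#' @return the updated [CycleNet-class].
#' @export
loadEncoderWeights <- function(net, weights) {
  for (nm in names(weights)) {
    if (!nm %in% names(net@params))
      stop("unknown parameter name: ", nm)
    if (!identical(dim(net@params[[nm]]), dim(weights[[nm]])) ||
        length(net@params[[nm]]) != length(weights[[nm]]))
      stop("shape mismatch for parameter: ", nm)
    net@params[[nm]] <- weights[[nm]]
  }
  net
}

# stack a list of equally shaped single-channel volumes/images into the
# engine's (S*N) x 1 activation layout
.stackInput <- function(vols, arch) {
  nd <- if (arch == "3d") 3L else 2L
  d1 <- dim(vols[[1]])
  if (is.null(d1) || length(d1) != nd)
    stop(sprintf("%s network expects single-channel %d-D inputs", arch, nd))
  if (any(d1 < 16L))
    stop("every spatial dimension must be at least 16, got ",
         paste(d1, collapse = "x"))
  for (v in vols)
    if (!identical(dim(v), d1)) stop("all inputs in a batch must share one shape")
  x <- matrix(as.numeric(unlist(vols, use.names = FALSE)), ncol = 1L)
  list(x = x, spdim = d1, N = length(vols))
}

#' Forward pass of a cell cycle network
#'
#' Runs a batch of single-channel volumes (3D net) or images (2D net)
#' through the network. Any input with every spatial dimension >= 16 is
#' admissible; the global max-pool head always reduces to one scalar per
#' sample. With \code{train = FALSE} dropout is disabled and the pass is
#' deterministic for fixed weights.
#'
#' @param net a [CycleNet-class].
#' @param vols list of (Z, Y, X) arrays (or (Y, X) matrices for the 2D
#'   net), all of one shape.
#' @param train enable dropout (and retain the backward cache).
#' @return list with \code{out} (numeric, one scalar per sample: logit or
#'   angle) and, when \code{train}, \code{cache} for [netBackward()].
#' @export
netForward <- function(net, vols, train = FALSE) {
  st <- .stackInput(vols, net@arch)
  x <- st$x
  spdim <- st$spdim
  N <- st$N
  p <- net@params
  caches <- if (train) vector("list", length(net@layers)) else NULL
  for (li in seq_along(net@layers)) {
    ly <- net@layers[[li]]
    S <- prod(spdim)
    if (ly$type == "gn") {
      r <- .nnGnFwd(x, p[[paste0(ly$tag, "_gn_gamma")]],
                    p[[paste0(ly$tag, "_gn_beta")]], ly$groups, S, N)
      if (train) caches[[li]] <- list(xhat = r$xhat, invstd = r$invstd,
                                      S = S)
      x <- r$y
    } else if (ly$type == "conv") {
      r <- .nnConvFwd(x, p[[paste0(ly$tag, "_conv_w")]],
                      if (ly$bias) p[[paste0(ly$tag, "_conv_b")]] else NULL,
                      spdim, N, keep = train, tag = ly$tag)
      if (train) caches[[li]] <- list(P = r$P, spdim = spdim)
      x <- r$y
    } else if (ly$type == "relu") {
      if (train) caches[[li]] <- list(pos = x > 0)
      x <- x * (x > 0)
    } else if (ly$type == "pool") {
      r <- .nnPoolFwd(x, spdim, N)
      if (train) caches[[li]] <- r
      x <- r$y
      spdim <- r$d2
    } else if (ly$type == "gmax") {
      r <- .nnGlobalMaxFwd(x, S, N)
      if (train) caches[[li]] <- list(wh = r$wh, S = S)
      x <- r$y  # now N x C
    } else if (ly$type == "dropout") {
      if (train) {
        keep <- matrix(runif(length(x)) > ly$p, nrow(x), ncol(x))
        caches[[li]] <- list(keep = keep)
        x <- x * keep / (1 - ly$p)
      }
    } else if (ly$type == "linear") {
      if (train) caches[[li]] <- list(h = x)
      x <- x %*% p[["head_w"]] + p[["head_b"]]
    }
  }
  list(out = as.numeric(x),
       cache = if (train) list(caches = caches, N = N) else NULL)
}

#' Backward pass: parameter gradients from output gradients
#'
#' Backpropagates \code{dout} (the gradient of the loss w.r.t. each
#' sample's scalar output) through the cached forward pass of
#' [netForward()] with \code{train = TRUE}.
#'
#' @param net a [CycleNet-class].
#' @param cache the \code{cache} element returned by [netForward()].
#' @param dout numeric, one gradient per sample.
#' @return named list of gradients matching \code{netParams(net)}.
#' @export
netBackward <- function(net, cache, dout) {
  p <- net@params
  caches <- cache$caches
  N <- cache$N
  grads <- list()
  d <- matrix(dout, ncol = 1L)
  for (li in rev(seq_along(net@layers))) {
    ly <- net@layers[[li]]
    cc <- caches[[li]]
    if (ly$type == "linear") {
      grads[["head_w"]] <- crossprod(cc$h, d)
      grads[["head_b"]] <- colSums(d)
      d <- d %*% t(p[["head_w"]])
    } else if (ly$type == "dropout") {
      if (!is.null(cc)) d <- d * cc$keep / (1 - ly$p)
    } else if (ly$type == "gmax") {
      d <- .nnGlobalMaxBwd(d, cc, cc$S, N)
    } else if (ly$type == "pool") {
      d <- .nnPoolBwd(d, cc, N)
    } else if (ly$type == "relu") {
      d <- d * cc$pos
    } else if (ly$type == "conv") {
      r <- .nnConvBwd(d, p[[paste0(ly$tag, "_conv_w")]], cc$P, cc$spdim, N,
                      tag = ly$tag)
      grads[[paste0(ly$tag, "_conv_w")]] <- r$dW
      if (ly$bias) grads[[paste0(ly$tag, "_conv_b")]] <- r$db
      d <- r$dx
    } else if (ly$type == "gn") {
      r <- .nnGnBwd(d, cc, p[[paste0(ly$tag, "_gn_gamma")]], ly$groups,
                    cc$S, N)
      grads[[paste0(ly$tag, "_gn_gamma")]] <- r$dgamma
      grads[[paste0(ly$tag, "_gn_beta")]] <- r$dbeta
      d <- r$dx
    }
  }
  grads
}

#' Predicted scores for a set of volumes
#'
#' Deterministic forward passes in evaluation mode, batched for speed.
#' Classification nets return logits; apply \code{plogis} for
#' probabilities. Regression nets return predicted angles in degrees.
#'
#' @param net a [CycleNet-class].
#' @param vols list of inputs (see [netForward()]).
#' @param batchSize evaluation batch size.
#' @return numeric vector, one scalar per input.
#' @export
netPredict <- function(net, vols, batchSize = 8L) {
  out <- numeric(length(vols))
  i <- 1L
  while (i <= length(vols)) {
    j <- min(i + batchSize - 1L, length(vols))
    out[i:j] <- netForward(net, vols[i:j], train = FALSE)$out
    i <- j + 1L
  }
  out
}
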