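#' Domain-aware attention over feature maps
#'
#' An inference-only channel-attention operator for scene/lighting
#' adaptation. Three effective squeeze-and-excitation (ESE) branches — each
#' a single fully connected C x C layer on the globally average-pooled
#' channel vector — produce three candidate channel descriptors. A softmax
#' over a 3 x C domain projection of the same pooled vector yields domain
#' weights on the probability simplex, whose convex combination of the
#' branch descriptors forms the domain-adaptive response. The input map is
#' finally rescaled channel-wise by the sigmoid of that response, so every
#' output entry is strictly attenuated relative to the input.
#'
#' Feature maps are numeric arrays of shape `C x H x W` (channels first).
#' Parameters are supplied, never trained here.
#'
#' @name daa
NULL

check_feature_map <- function(F) {
  if (!is.array(F) || length(dim(F)) != 3L) {
    stop("feature map must be a C x H x W array", call. = FALSE)
  }
  if (!all(is.finite(F))) stop("feature map must be finite", call. = FALSE)
  invisible(F)
}

#' Parameters of the domain-aware attention operator
#'
#' @param domain_fc a 3 x C matrix projecting the pooled channel vector to
#'   the three domain logits
#' @param ese_fcs a list of three C x C matrices, one per ESE branch
#' @param ese_biases a list of three length-C bias vectors (defaults to
#'   zeros)
#' @return a list with class `daa_params`
#' @export
daa_params <- function(domain_fc, ese_fcs, ese_biases = NULL) {
  domain_fc <- as.matrix(domain_fc)
  if (nrow(domain_fc) != 3L) stop("domain_fc must have 3 rows", call. = FALSE)
  C <- ncol(domain_fc)
  if (length(ese_fcs) != 3L) stop("need exactly three ESE branches", call. = FALSE)
  ese_fcs <- lapply(ese_fcs, as.matrix)
  for (m in ese_fcs) {
    if (!all(dim(m) == c(C, C))) stop("each ESE matrix must be C x C", call. = FALSE)
  }
  if (is.null(ese_biases)) ese_biases <- rep(list(numeric(C)), 3L)
  if (length(ese_biases) != 3L || any(lengths(ese_biases) != C)) {
    stop("need three length-C ESE biases", call. = FALSE)
  }
  if (!all(is.finite(domain_fc)) ||
      !all(vapply(ese_fcs, function(m) all(is.finite(m)), logical(1))) ||
      !all(vapply(ese_biases, function(b) all(is.finite(b)), logical(1)))) {
    stop("DAA parameters must be finite", call. = FALSE)
  }
  structure(list(domain_fc = domain_fc, ese_fcs = ese_fcs,
                 ese_biases = lapply(ese_biases, as.numeric), C = C),
            class = "daa_params")
}

#' Global average pooling of a feature map
#'
#' @param F a `C x H x W` array
#' @return a length-C vector of per-channel spatial means
#' @export
global_avg_pool <- function(F) {
  check_feature_map(F)
  apply(F, 1L, mean)
}

#' One ESE branch: fully connected layer on the pooled vector
#'
#' Returns the pre-activation channel descriptor
#' `fc %*% global_avg_pool(F) + bias`; the nonlinearity is deferred to the
#' final sigmoid scaling so the descriptor is not saturated twice.
#'
#' @param F a `C x H x W` array
#' @param fc a C x C weight matrix
#' @param bias a length-C bias vector
#' @return a length-C descriptor
#' @export
ese_branch <- function(F, fc, bias = NULL) {
  pooled <- global_avg_pool(F)
  fc <- as.matrix(fc)
  C <- length(pooled)
  if (!all(dim(fc) == c(C, C))) {
    stop("ESE weight matrix must be ", C, " x ", C, call. = FALSE)
  }
  if (is.null(bias)) bias <- numeric(C)
  if (length(bias) != C) stop("bias must have length ", C, call. = FALSE)
  as.vector(fc %*% pooled) + bias
}

softmax <- function(x) {
  e <- exp(x - max(x))
  e / sum(e)
}

#' Domain weights of a feature map
#'
#' Softmax (numerically stabilized by max subtraction) of the domain
#' projection of the pooled channel vector; the result lies on the
#' 3-simplex.
#'
#' @param F a `C x H x W` array
#' @param params a [daa_params()]
#' @return a length-3 vector of nonnegative weights summing to 1
#' @export
domain_weights <- function(F, params) {
  stopifnot(inherits(params, "daa_params"))
  pooled <- global_avg_pool(F)
  if (length(pooled) != params$C) {
    stop("feature map has ", length(pooled), " channels; parameters expect ",
         params$C, call. = FALSE)
  }
  softmax(as.vector(params$domain_fc %*% pooled))
}

#' Forward pass of the domain-aware attention operator
#'
#' Stacks the three ESE branch descriptors, combines them with the domain
#' weights into the domain-adaptive response vector, and multiplies each
#' input channel by the sigmoid of its response component.
#'
#' @param F a `C x H x W` array
#' @param params a [daa_params()]
#' @return an array of the same shape as `F`
#' @export
daa_forward <- function(F, params) {
  stopifnot(inherits(params, "daa_params"))
  check_feature_map(F)
  C <- dim(F)[1L]
  if (C != params$C) {
    stop("feature map has ", C, " channels; parameters expect ", params$C,
         call. = FALSE)
  }
  w <- domain_weights(F, params)
  SC <- vapply(1:3, function(b) ese_branch(F, params$ese_fcs[[b]],
                                           params$ese_biases[[b]]),
               numeric(C))                          # C x 3 stack
  sdc <- as.vector(SC %*% w)                        # convex combination
  scale <- 1 / (1 + exp(-sdc))
  F * array(scale, dim = dim(F))                    # channel-wise rescaling
}

#' Read / write DAA parameters
#'
#' Parameters travel as a plain JSON document holding `domain_fc`,
#' `ese_fcs` (list of three matrices) and `ese_biases`; shapes are
#' validated on load.
#'
#' @param path file path
#' @param params a [daa_params()] (for writing)
#' @return `read_daa_params()` returns a [daa_params()].
#' @export
read_daa_params <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  x <- jsonlite::fromJSON(path, simplifyMatrix = TRUE)
  daa_params(x$domain_fc,
             lapply(seq_len(3), function(b) x$ese_fcs[b, , ]),
             if (!is.null(x$ese_biases)) {
               lapply(seq_len(3), function(b) x$ese_biases[b, ])
             })
}

#' @rdname read_daa_params
#' @export
write_daa_params <- function(params, path) {
  stopifnot(inherits(params, "daa_params"))
  x <- list(domain_fc = params$domain_fc,
            ese_fcs = aperm(array(unlist(params$ese_fcs),
                                  dim = c(params$C, params$C, 3L)), c(3, 1, 2)),
            ese_biases = do.call(rbind, params$ese_biases))
  atomic_write(path, function(p) {
    jsonlite::write_json(x, p, digits = NA, auto_unbox = TRUE)
  })
  invisible(path)
}
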