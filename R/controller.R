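# Controller genotypes: 86 parameters (18x4 input-hidden weights, 4 hidden
# biases, 4x2 hidden-output weights, 2 output biases), each encoded as 8
# bits, giving a 688-bit genotype. Bytes map linearly onto [-5, +5].

N_PARAMS <- 86L
BITS_PER_PARAM <- 8L
GENOTYPE_LENGTH <- N_PARAMS * BITS_PER_PARAM  # 688

#' Number of bits in a controller genotype (688)
#' @return Integer scalar.
#' @export
genotype_length <- function() GENOTYPE_LENGTH

#' Draw a random genotype
#'
#' Initial genotypes are i.i.d. uniform random bits, drawn from R's current
#' RNG stream (seed with [set.seed()] for reproducibility).
#'
#' @param n Number of genotypes to draw.
#' @return A single integer 0/1 vector of length 688 if \code{n = 1},
#'   otherwise a list of such vectors.
#' @export
random_genotype <- function(n = 1) {
  g <- lapply(seq_len(n), function(i)
    sample(c(0L, 1L), GENOTYPE_LENGTH, replace = TRUE))
  if (n == 1) g[[1]] else g
}

check_genotype <- function(bits) {
  if (length(bits) != GENOTYPE_LENGTH || !all(bits %in% c(0L, 1L)))
    stop("corrupt genotype: expected ", GENOTYPE_LENGTH, " bits")
  invisible(bits)
}

# bytes of a genotype, MSB-first within each 8-bit group
genotype_bytes <- function(bits) {
  check_genotype(bits)
  m <- matrix(as.integer(bits), nrow = BITS_PER_PARAM)
  as.integer(colSums(m * 2^((BITS_PER_PARAM - 1):0)))
}

#' Decode a genotype into network parameters
#'
#' Consecutive 8-bit groups (MSB first) are read as unsigned bytes
#' b in 0..255 and mapped linearly to weights w = -5 + 10 b / 255. Parameter
#' order: input-to-hidden weights row-major by input index, hidden biases,
#' hidden-to-output weights row-major by hidden index, output biases.
#'
#' @param bits Integer 0/1 vector of length 688.
#' @return A \code{network_params} object: list with \code{W1} (18 x 4),
#'   \code{b1} (4), \code{W2} (4 x 2), \code{b2} (2), and the flat
#'   86-parameter vector \code{theta}.
#' @examples
#' g <- rep(0L, genotype_length())
#' decode_genotype(g)$theta[1]  # byte 0 -> -5
#' @export
decode_genotype <- function(bits) {
  b <- genotype_bytes(bits)
  theta <- -5 + 10 * b / 255
  structure(list(
    W1 = matrix(theta[1:72], nrow = 18, ncol = 4, byrow = TRUE),
    b1 = theta[73:76],
    W2 = matrix(theta[77:84], nrow = 4, ncol = 2, byrow = TRUE),
    b2 = theta[85:86],
    theta = theta
  ), class = "network_params")
}

#' Encode network parameters back into a genotype
#'
#' Inverse of [decode_genotype()] up to the 8-bit quantization: each
#' parameter is mapped to the nearest byte b = round((w + 5) * 255 / 10) and
#' written MSB-first. Round-trips exactly on decoded values.
#'
#' @param params A \code{network_params} object (or a flat 86-vector).
#' @return Integer 0/1 vector of length 688.
#' @export
encode_genotype <- function(params) {
  theta <- if (inherits(params, "network_params")) params$theta else params
  stopifnot(length(theta) == N_PARAMS)
  b <- as.integer(pmin(255, pmax(0, round((theta + 5) * 255 / 10))))
  bits <- vapply(b, function(v) as.integer(intToBits(v)[8:1]), integer(8))
  as.integer(bits)
}

#' Feed-forward pass of the neural controller
#'
#' A 24-neuron feed-forward network: 18 inputs (15 retina components, 2
#' smell lines, 1 ground value), 4 logistic hidden units, 2 logistic outputs.
#' Each output o in (0, 1) maps symmetrically onto a wheel speed
#' (2 o - 1) * wheel_speed_max, so o = 0.5 is a stopped wheel.
#'
#' @param params A \code{network_params} from [decode_genotype()].
#' @param inputs Numeric vector of 18 sensor values in \code{[0, 1]}.
#' @param config An [arena_config()] (supplies \code{wheel_speed_max}).
#' @return Numeric \code{c(v_left, v_right)}, each bounded by
#'   \code{wheel_speed_max} in absolute value.
#' @export
forward_controller <- function(params, inputs, config) {
  stopifnot(length(inputs) == 18)
  h <- plogis(drop(crossprod(params$W1, inputs)) + params$b1)
  o <- plogis(drop(crossprod(params$W2, h)) + params$b2)
  v <- (2 * o - 1) * config$wheel_speed_max
  c(v_left = v[1], v_right = v[2])
}

# 86 x 4 parameter matrix for the compiled trial loop
team_param_matrix <- function(genotypes) {
  stopifnot(length(genotypes) == 4)
  vapply(genotypes, function(g) decode_genotype(g)$theta, numeric(N_PARAMS))
}
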