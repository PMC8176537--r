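#' Surface-tension constants for the output layer
#'
#' The output layer of the network contains one "tension neuron" per risk
#' level. Each neuron holds the surface tension of a reference liquid
#' (mN/m at 20 degrees C); the default four are ethanol (22.1), ethylene
#' glycol (47.7), water (72.8) and mercury (425.41), ordered from the
#' easiest to the hardest surface to break. Classification follows the
#' physical analogy gamma = F / (2L): a subject's learned mass `m` and
#' perimeter `Per` give a weight `m * g` pressing on each surface, and a
#' level's surface is broken when that weight overcomes the restoring
#' force `T_k * Per`. Higher risk levels therefore require breaking
#' progressively harder surfaces.
#'
#' @param tensions Numeric vector of exactly four positive surface
#'   tensions, one per risk level (mN/m at 20 degrees C).
#' @param gravity Positive gravitational constant (m/s^2).
#' @return An object of class `"tension_constants"`.
#' @examples
#' tension_constants()
#' @export
tension_constants <- function(tensions = c(22.1, 47.7, 72.8, 425.41),
                              gravity = 9.8) {
  if (length(tensions) != 4 || !is.numeric(tensions) || any(!is.finite(tensions)) ||
      any(tensions <= 0)) {
    stop_pstnn("invalid_architecture",
               "`tensions` must be four finite, strictly positive values")
  }
  if (!is.numeric(gravity) || length(gravity) != 1 || !is.finite(gravity) ||
      gravity <= 0) {
    stop_pstnn("invalid_architecture", "`gravity` must be a single positive value")
  }
  structure(list(tensions = as.numeric(tensions), gravity = as.numeric(gravity)),
            class = "tension_constants")
}

#' Dense layer parameters
#'
#' Weight matrix and bias vector of one fully connected layer; rows index
#' output neurons, columns index inputs.
#'
#' @param weights Numeric matrix, `neurons_out x neurons_in`.
#' @param biases Numeric vector of length `neurons_out`.
#' @return An object of class `"dense_layer"`.
#' @export
dense_layer <- function(weights, biases) {
  weights <- as.matrix(weights)
  biases <- as.numeric(biases)
  if (nrow(weights) != length(biases)) {
    stop_pstnn("shape", "weight rows (%d) must equal bias length (%d)",
               nrow(weights), length(biases))
  }
  if (any(!is.finite(weights)) || any(!is.finite(biases))) {
    stop_pstnn("shape", "layer parameters must be finite")
  }
  structure(list(weights = weights, biases = biases), class = "dense_layer")
}

#' Assemble a surface-tension network
#'
#' A network is three dense layers plus the tension constants. Layers 1
#' and 2 use the hyperbolic tangent transfer; layer 3 is linear and has
#' exactly two output neurons, interpreted as mass and perimeter, which
#' feed the four tension neurons.
#'
#' @param layer1,layer2,layer3 [dense_layer()] objects whose dimensions
#'   chain: layer 1 input width is `n_inputs`, layer 2 consumes layer 1's
#'   output, layer 3 consumes layer 2's output and has two neurons.
#' @param tension A [tension_constants()] object.
#' @param n_inputs Number of input features.
#' @return An object of class `"pst_network"`.
#' @seealso [init_nguyen_widrow()] for the standard constructor.
#' @export
pst_network <- function(layer1, layer2, layer3,
                        tension = tension_constants(),
                        n_inputs = ncol(layer1$weights)) {
  for (l in list(layer1, layer2, layer3)) {
    if (!inherits(l, "dense_layer")) stop_pstnn("shape", "layers must be dense_layer objects")
  }
  if (ncol(layer1$weights) != n_inputs) {
    stop_pstnn("shape", "layer 1 expects %d inputs, network declares %d",
               ncol(layer1$weights), n_inputs)
  }
  if (ncol(layer2$weights) != nrow(layer1$weights) ||
      ncol(layer3$weights) != nrow(layer2$weights)) {
    stop_pstnn("shape", "layer dimensions do not chain")
  }
  if (nrow(layer3$weights) != 2) {
    stop_pstnn("invalid_architecture",
               "layer 3 must have exactly 2 neurons (mass, perimeter)")
  }
  structure(list(layer1 = layer1, layer2 = layer2, layer3 = layer3,
                 tension = tension, n_inputs = as.integer(n_inputs)),
            class = "pst_network")
}

#' @export
print.pst_network <- function(x, ...) {
  sizes <- layer_sizes(x)
  cat("Surface-tension neural network\n")
  cat(sprintf("  architecture: %s (+ 4 tension neurons)\n",
              paste(sizes, collapse = "-")))
  cat(sprintf("  tensions (mN/m): %s; g = %g m/s^2\n",
              paste(x$tension$tensions, collapse = ", "), x$tension$gravity))
  cat(sprintf("  parameters: %d\n", n_parameters(x)))
  invisible(x)
}

layer_sizes <- function(net) {
  c(net$n_inputs, nrow(net$layer1$weights), nrow(net$layer2$weights),
    nrow(net$layer3$weights))
}

n_parameters <- function(net) {
  sum(vapply(list(net$layer1, net$layer2, net$layer3),
             function(l) length(l$weights) + length(l$biases), numeric(1)))
}

#' Nguyen-Widrow network initialization
#'
#' Initializes a network so that the active regions of the tanh neurons
#' are spread roughly uniformly over the input space: each hidden-layer
#' weight row is scaled to Euclidean norm `beta = 0.7 * H^(1/I)` (`H`
#' neurons, `I` inputs) and biases are drawn uniformly in `[-beta, beta]`.
#' The linear mass/perimeter head uses small weights (uniform
#' `[-0.5, 0.5] / sqrt(I)`) and positive biases (uniform `[1, 2]`) so
#' that every subject starts with mass and perimeter positive at order
#' 1 — inside the tension layer's active region rather than beyond its
#' pole at zero perimeter.
#'
#' @param sizes Integer vector `(n_inputs, hidden1, hidden2, 2)`; the last
#'   entry must be 2 (mass and perimeter neurons). Default 20-80-80-2.
#' @param seed Integer seed; identical seeds give bit-identical networks.
#' @param tension A [tension_constants()] object.
#' @return A [pst_network()].
#' @examples
#' net <- init_nguyen_widrow(c(20, 80, 80, 2), seed = 1)
#' sqrt(sum(net$layer1$weights[1, ]^2))  # 0.7 * 80^(1/20)
#' @export
init_nguyen_widrow <- function(sizes = c(20, 80, 80, 2), seed = 0L,
                               tension = tension_constants()) {
  if (length(sizes) != 4 || any(sizes != round(sizes)) || any(sizes <= 0)) {
    stop_pstnn("invalid_architecture",
               "`sizes` must be four positive integers (inputs, hidden, hidden, 2)")
  }
  if (sizes[4] != 2) {
    stop_pstnn("invalid_architecture", "the final layer must have 2 neurons")
  }
  set.seed(seed)
  nw_layer <- function(n_in, n_out) {
    beta <- 0.7 * n_out^(1 / n_in)
    w <- matrix(runif(n_out * n_in, -1, 1), n_out, n_in)
    norms <- sqrt(rowSums(w^2))
    norms[norms == 0] <- 1
    w <- w * (beta / norms)
    dense_layer(w, runif(n_out, -beta, beta))
  }
  # linear mass/perimeter head: weights at 1/sqrt(n_in) scale and
  # positive unit-scale biases start every subject's mass and perimeter
  # positive at order 1, i.e. in the tension layer's active region
  # (a symmetric start puts half the cohort at negative perimeter, on
  # the wrong side of the activation's pole)
  lin_layer <- function(n_in, n_out) {
    dense_layer(matrix(runif(n_out * n_in, -0.5, 0.5) / sqrt(n_in), n_out, n_in),
                runif(n_out, 1, 2))
  }
  pst_network(nw_layer(sizes[1], sizes[2]),
              nw_layer(sizes[2], sizes[3]),
              lin_layer(sizes[3], 2),
              tension = tension, n_inputs = sizes[1])
}

#' Hyperbolic tangent transfer function
#'
#' Elementwise `2 / (1 + exp(-2 y)) - 1`; values lie strictly inside
#' (-1, 1) and saturate smoothly for large |y|.
#'
#' @param y Numeric vector.
#' @return Numeric vector of the same length.
#' @export
tanh_transfer <- function(y) {
  2 / (1 + exp(-2 * y)) - 1
}

#' Dense layer pre-activation
#'
#' `weights %*% x + biases` for one layer: the weighted sum each neuron
#' computes before its transfer function.
#'
#' @param layer A [dense_layer()].
#' @param x Numeric vector matching the layer input width.
#' @return Numeric vector, one value per neuron.
#' @export
dense_preactivation <- function(layer, x) {
  if (length(x) != ncol(layer$weights)) {
    stop_pstnn("shape", "input length %d does not match layer width %d",
               length(x), ncol(layer$weights))
  }
  drop(layer$weights %*% x) + layer$biases
}

# exponent clamp: guards exp() against double overflow; invisible at
# realistic magnitudes (|arg| < 500 for any sane mass/perimeter)
EXP_CLAMP <- 500

#' Surface-tension output activation
#'
#' For a mass `m` and perimeter `Per`, each tension neuron computes
#' `O_k = 1 - exp(-m * g / (T_k * Per))`: the degree to which the
#' subject's weight breaks the k-th liquid surface. As
#' `m * g / (T_k * Per)` grows the activation tends to 1 (surface broken)
#' and as it vanishes the activation tends to 0. The exponent is clamped
#' to [-500, 500] before exponentiation for numerical safety.
#'
#' @param m Mass output of layer 3 (finite real; may be negative during
#'   training).
#' @param Per Perimeter output of layer 3 (finite, nonzero).
#' @param c A [tension_constants()] object.
#' @return Numeric vector of four activations, each < 1; when `m > 0` and
#'   `Per > 0` the values are in (0, 1) and non-increasing across levels.
#' @examples
#' surface_tension_activation(1, 1, tension_constants())
#' @export
surface_tension_activation <- function(m, Per, c = tension_constants()) {
  if (!is.finite(m) || !is.finite(Per)) {
    stop_pstnn("invalid_output", "mass and perimeter must be finite")
  }
  if (Per == 0) {
    stop_pstnn("degenerate_geometry",
               "perimeter is zero: surface-tension activation undefined")
  }
  z <- -m * c$gravity / (c$tensions * Per)
  1 - exp(pmin(pmax(z, -EXP_CLAMP), EXP_CLAMP))
}

#' Forward pass through the network
#'
#' Runs one input vector through the three dense layers and the tension
#' layer, retaining every intermediate quantity needed by
#' backpropagation.
#'
#' @param net A [pst_network()].
#' @param x Numeric input vector of length `net$n_inputs` (expected
#'   normalized to \[0, 1\]).
#' @return An object of class `"forward_trace"`: a list with `input`,
#'   pre-activations `y1`, `y2`, transfers `Y1`, `Y2`, the linear layer-3
#'   output `Y3 = c(m, Per)` and the tension activations `O`.
#' @export
forward_pass <- function(net, x) {
  x <- as.numeric(x)
  y1 <- dense_preactivation(net$layer1, x)
  Y1 <- tanh_transfer(y1)
  y2 <- dense_preactivation(net$layer2, Y1)
  Y2 <- tanh_transfer(y2)
  Y3 <- dense_preactivation(net$layer3, Y2)
  O <- surface_tension_activation(Y3[1], Y3[2], net$tension)
  structure(list(input = x, y1 = y1, Y1 = Y1, y2 = y2, Y2 = Y2,
                 Y3 = c(m = Y3[[1]], Per = Y3[[2]]), O = O),
            class = "forward_trace")
}

# vectorized forward over a matrix of inputs (rows = subjects); used by
# training and prediction where per-sample traces are not needed
forward_batch <- function(net, X) {
  X <- as.matrix(X)
  if (ncol(X) != net$n_inputs) {
    stop_pstnn("shape", "input width %d does not match network inputs %d",
               ncol(X), net$n_inputs)
  }
  Y1 <- tanh_transfer(sweep(X %*% t(net$layer1$weights), 2, net$layer1$biases, "+"))
  Y2 <- tanh_transfer(sweep(Y1 %*% t(net$layer2$weights), 2, net$layer2$biases, "+"))
  Y3 <- sweep(Y2 %*% t(net$layer3$weights), 2, net$layer3$biases, "+")
  m <- Y3[, 1]; Per <- Y3[, 2]
  if (any(Per == 0)) {
    stop_pstnn("degenerate_geometry", "a sample produced perimeter zero")
  }
  g <- net$tension$gravity; Tk <- net$tension$tensions
  Z <- (-m * g / Per) %o% (1 / Tk)
  EZ <- exp(pmin(pmax(Z, -EXP_CLAMP), EXP_CLAMP))
  # gradient-safe exponential: the clamped activation is constant outside
  # the clamp, so its derivative there is zero
  EZg <- ifelse(abs(Z) < EXP_CLAMP, EZ, 0)
  list(Y1 = Y1, Y2 = Y2, m = m, Per = Per, EZ = EZ, EZg = EZg, O = 1 - EZ)
}

# cumulative target patterns, one row per risk level
risk_patterns <- function() {
  p <- matrix(0, 4, 4, dimnames = list(paste0("risk", 1:4), NULL))
  for (r in 1:4) p[r, seq_len(r)] <- 1
  p
}

#' Encode a risk level as a cumulative target pattern
#'
#' Level r's target activates the first r tension neurons: level 1 is
#' (1,0,0,0), level 4 — which breaks all four surfaces — is (1,1,1,1).
#'
#' @param level Integer risk level in 1..4.
#' @return An object of class `"risk_target"` with fields `level` and
#'   `pattern` (binary vector of length 4).
#' @export
encode_risk <- function(level) {
  if (length(level) != 1 || is.na(level) || level != round(level) ||
      level < 1 || level > 4) {
    stop_pstnn("invalid_label", "risk level must be an integer in 1..4, got %s",
               paste(level, collapse = ","))
  }
  structure(list(level = as.integer(level), pattern = risk_patterns()[level, ]),
            class = "risk_target")
}

#' Continuous class scores from the tension activations
#'
#' Score for level r is the negative squared distance between the output
#' vector and level r's cumulative target pattern; higher means more
#' r-like. [decode_risk()] is the argmax of these scores with ties broken
#' toward the lower level.
#'
#' @param O Numeric vector of four tension activations.
#' @return Numeric vector of four scores (all <= 0; 0 means exact match).
#' @export
class_scores <- function(O) {
  if (length(O) != 4 || any(!is.finite(O))) {
    stop_pstnn("invalid_output", "`O` must be four finite activations")
  }
  P <- risk_patterns()
  -colSums((t(P) - O)^2)
}

# matrix version: rows of Omat are output vectors -> n x 4 score matrix
class_scores_matrix <- function(Omat) {
  P <- risk_patterns()
  sq <- rowSums(Omat^2)
  S <- -(outer(sq, rowSums(P^2), "+") - 2 * Omat %*% t(P))
  colnames(S) <- rownames(P)
  S
}

#' Decode tension activations to a risk level
#'
#' Returns the level whose cumulative target pattern is nearest to `O` in
#' squared distance, ties broken toward the lower level.
#'
#' @param O Numeric vector of four tension activations.
#' @return Integer risk level in 1..4.
#' @export
decode_risk <- function(O) {
  which.max(class_scores(O))[[1]]
}

#' Predict risk levels for a matrix of inputs
#'
#' @param object A [pst_network()].
#' @param newdata Numeric matrix, subjects in rows, `n_inputs` columns.
#' @param type `"level"` for decoded risk levels, `"scores"` for the
#'   n x 4 class-score matrix, `"activations"` for the raw tension
#'   outputs.
#' @param ... Unused.
#' @return Integer vector or numeric matrix according to `type`.
#' @export
predict.pst_network <- function(object, newdata,
                                type = c("level", "scores", "activations"),
                                ...) {
  type <- match.arg(type)
  fb <- forward_batch(object, newdata)
  if (type == "activations") return(fb$O)
  S <- class_scores_matrix(fb$O)
  if (type == "scores") return(S)
  max.col(S, ties.method = "first")
}
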