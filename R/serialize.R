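#' Write a network (and fitted preprocessing state) to JSON
#'
#' The model document stores layer sizes, row-major weight matrices,
#' biases, the tension constants, and optionally the normalization
#' parameters, selected input columns and training metadata, so a saved
#' model can be applied to a raw cohort CSV without refitting anything.
#' Numbers are written at full double precision; a load/save round trip
#' reproduces forward-pass outputs exactly.
#'
#' @param net A [pst_network()].
#' @param path Output file path.
#' @param normalization Optional `"normalization_params"` object.
#' @param selected Optional character vector of selected input columns.
#' @param training Optional list of training metadata (seed, stop reason,
#'   iterations, final MSE, ...).
#' @return `path`, invisibly.
#' @export
write_pst_model <- function(net, path, normalization = NULL, selected = NULL,
                            training = NULL) {
  lay <- function(l) list(weights = as.vector(t(l$weights)),
                          biases = l$biases)
  doc <- list(
    format = "pstnn-model",
    version = 1L,
    layer_sizes = layer_sizes(net),
    layers = list(lay(net$layer1), lay(net$layer2), lay(net$layer3)),
    tensions = net$tension$tensions,
    gravity = net$tension$gravity
  )
  if (!is.null(normalization)) {
    doc$normalization <- list(feature = normalization$feature,
                              min = normalization$min,
                              max = normalization$max)
  }
  if (!is.null(selected)) doc$selected_columns <- as.character(selected)
  if (!is.null(training)) doc$training <- training
  # digits = I(17): shortest exact decimal representation of a double,
  # so the round trip is bit-exact
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = I(17),
                       null = "null")
  invisible(path)
}

#' Read a network saved by [write_pst_model()]
#'
#' @param path Path to the model JSON.
#' @return A [pst_network()] with attributes `"normalization"`,
#'   `"selected_columns"` and `"training"` when they were stored.
#' @export
read_pst_model <- function(path) {
  doc <- tryCatch(jsonlite::read_json(path, simplifyVector = TRUE,
                                      simplifyDataFrame = FALSE),
                  error = function(e) {
    stop_pstnn("parse", "cannot parse model file '%s': %s", path, conditionMessage(e))
  })
  if (!identical(doc$format, "pstnn-model")) {
    stop_pstnn("parse", "'%s' is not a pstnn model document", path)
  }
  sz <- as.integer(doc$layer_sizes)
  mk <- function(i, n_out, n_in) {
    dense_layer(matrix(doc$layers[[i]]$weights, n_out, n_in, byrow = TRUE),
                doc$layers[[i]]$biases)
  }
  net <- pst_network(mk(1, sz[2], sz[1]), mk(2, sz[3], sz[2]), mk(3, sz[4], sz[3]),
                     tension = tension_constants(doc$tensions, doc$gravity),
                     n_inputs = sz[1])
  if (!is.null(doc$normalization)) {
    attr(net, "normalization") <- structure(
      list(feature = doc$normalization$feature,
           min = doc$normalization$min,
           max = doc$normalization$max,
           constant = doc$normalization$max <= doc$normalization$min),
      class = "normalization_params")
  }
  if (!is.null(doc$selected_columns)) {
    attr(net, "selected_columns") <- doc$selected_columns
  }
  if (!is.null(doc$training)) attr(net, "training") <- doc$training
  net
}
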