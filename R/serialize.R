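#' Serialize a trained model to JSON
#'
#' Writes a self-contained JSON container: support vectors, signed dual
#' coefficients, bias, kernel bandwidth and class penalties — everything
#' [decision_value()] needs. Multilevel models additionally record the final
#' (C, gamma) and hierarchy depth. The schema is stable: fields
#' `type`, `gamma`, `b`, `dual_coefs`, `support_vectors`, `weights`,
#' `training_size`, and for multilevel models `C` and `depth`.
#'
#' @param model a `wsvm_model` or `mlsvm_model`.
#' @param path output file path.
#' @export
write_model_json <- function(model, path) {
  if (inherits(model, "mlsvm_model")) {
    inner <- model$model
    obj <- list(type = "mlsvm_model", C = model$C, gamma = model$gamma,
                depth = model$depth)
  } else if (inherits(model, "wsvm_model")) {
    inner <- model
    obj <- list(type = "wsvm_model")
  } else stop("unsupported model class")
  obj$gamma <- inner$gamma
  obj$b <- inner$b
  obj$dual_coefs <- inner$dual_coefs
  obj$support_vectors <- unname(inner$support_vectors)
  obj$weights <- unclass(inner$weights)
  obj$training_size <- inner$training_size
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Load a model serialized with [write_model_json()]
#'
#' @param path JSON file path.
#' @return A `wsvm_model` (the decision-function part of a multilevel
#'   model round-trips as its final classifier).
#' @export
read_model_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  w <- structure(obj$weights, class = "weight_config")
  structure(list(support_vectors = as.matrix(obj$support_vectors),
                 support_indices = NA_integer_,
                 dual_coefs = as.numeric(obj$dual_coefs),
                 b = obj$b, gamma = obj$gamma, weights = w,
                 training_size = obj$training_size),
            class = "wsvm_model")
}
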