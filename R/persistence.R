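#' Save a fitted pathway-MKL model to JSON
#'
#' Serializes everything needed to reload the model and predict on new
#' samples: kernel weights per set name, dual coefficients and intercept,
#' per-set kernel widths and column indices, the standardized training
#' matrix backing the kernel expansion, the fit configuration, and (when
#' supplied) the training standardizer.
#'
#' @param model A `prognosit_model`.
#' @param path Output file path.
#' @param standardizer Optional `standardizer` fitted on the raw training
#'   data, stored alongside the model.
#' @return `path`, invisibly.
#' @seealso [load_prognosit_model()]
#' @export
save_prognosit_model <- function(model, path, standardizer = NULL) {
  stopifnot(inherits(model, "prognosit_model"))
  payload <- list(
    eta = as.list(model$eta),
    alpha = model$solution$alpha,
    b = model$solution$b,
    C = model$C, epsilon = model$epsilon, threshold = model$threshold,
    sigmas = as.list(model$stack$sigmas),
    indices = model$stack$indices,
    set_names = model$stack$set_names,
    x_train = model$stack$x_train,
    standardizer = if (!is.null(standardizer)) {
      list(center = standardizer$center, scale = standardizer$scale,
           zero_var = standardizer$zero_var)
    }
  )
  jsonlite::write_json(payload, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' Load a pathway-MKL model saved by [save_prognosit_model()]
#'
#' @param path Path to the JSON file.
#' @return List with `model` (a `prognosit_model` usable with `predict()`)
#'   and `standardizer` (or `NULL`).
#' @export
load_prognosit_model <- function(path) {
  p <- jsonlite::read_json(path, simplifyVector = TRUE)
  x_train <- as.matrix(p$x_train)
  stack <- structure(list(
    kernels = NULL,  # training kernels are not needed for prediction
    sigmas = unlist(p$sigmas),
    set_names = p$set_names,
    indices = lapply(p$indices, as.integer),
    x_train = x_train), class = "kernel_stack")
  sol <- structure(list(alpha_plus = pmax(p$alpha, 0),
                        alpha_minus = pmax(-p$alpha, 0),
                        alpha = p$alpha, b = p$b, objective = NA_real_,
                        C = p$C, epsilon = p$epsilon, tol = 1e-8),
                   class = "svr_solution")
  eta <- unlist(p$eta)
  model <- structure(list(eta = eta[stack$set_names], solution = sol,
                          trace = NULL, eta_trace = NULL,
                          selected = names(eta)[eta > p$threshold],
                          n_genes_used = NA_integer_, stack = stack,
                          threshold = p$threshold, C = p$C,
                          epsilon = p$epsilon, converged = NA,
                          degenerate = NA),
                     class = "prognosit_model")
  std <- if (!is.null(p$standardizer)) {
    structure(list(center = p$standardizer$center,
                   scale = p$standardizer$scale,
                   zero_var = p$standardizer$zero_var),
              class = "standardizer")
  }
  list(model = model, standardizer = std)
}
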