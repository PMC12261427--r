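# CSV and checkpoint I/O. The CSV dialect is comma-separated with a header
# row of feature names and one row per cell. Checkpoints are directories of
# plain JSON files so they are diffable and stable across platforms.

#' Read a cell-by-feature matrix from CSV
#'
#' @param path CSV file with a header row of feature names; rows are cells.
#' @return Numeric matrix.
#' @export
read_matrix_csv <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.csv(path, check.names = FALSE)
  X <- as.matrix(df)
  storage.mode(X) <- "double"
  if (!all(is.finite(X))) stop("non-finite values in ", path)
  X
}

#' Write a matrix to CSV
#'
#' @param X Numeric matrix (column names become the header; defaults to
#'   `f1..fd`).
#' @param path Output path.
#' @export
write_matrix_csv <- function(X, path) {
  X <- .as_points(X)
  if (is.null(colnames(X))) colnames(X) <- paste0("f", seq_len(ncol(X)))
  utils::write.csv(as.data.frame(X), path, row.names = FALSE)
  invisible(path)
}

.mat_to_list <- function(M) list(data = as.numeric(M), nrow = nrow(M), ncol = ncol(M))
# robust to jsonlite returning nested lists (simplifyVector = FALSE)
.list_to_mat <- function(x) {
  matrix(as.numeric(unlist(x$data)), as.integer(x$nrow), as.integer(x$ncol))
}

.serialize_potential <- function(net) {
  list(
    type = "lipschitz_potential",
    input_dim = net$input_dim, hidden = net$hidden,
    group_size = net$group_size, method = net$method,
    bjorck_iterations = net$bjorck_iterations,
    layers = lapply(net$layers, function(l) {
      list(raw = .mat_to_list(l$raw), bias = as.numeric(l$bias))
    })
  )
}

.deserialize_potential <- function(x) {
  net <- lipschitz_potential(x$input_dim, hidden = unlist(x$hidden),
                             group_size = x$group_size, method = x$method,
                             bjorck_iterations = x$bjorck_iterations, seed = 1L)
  params <- lapply(x$layers, function(l) {
    list(raw = .list_to_mat(l$raw), bias = as.numeric(unlist(l$bias)))
  })
  .potential_set_params(net, params)
}

.serialize_mlp <- function(net) {
  list(dims = net$dims,
       layers = lapply(net$layers, function(l) {
         list(W = .mat_to_list(l$W), b = as.numeric(l$b))
       }))
}

.deserialize_mlp <- function(x) {
  net <- .mlp_new(unlist(x$dims), seed = 1L)
  net$layers <- lapply(x$layers, function(l) {
    list(W = .list_to_mat(l$W), b = as.numeric(unlist(l$b)))
  })
  net
}

.write_json <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, null = "null")
}

#' Save a fitted transport model to a checkpoint directory
#'
#' Writes the potential, step-size and discriminator parameters, the optional
#' autoencoder, and a manifest (configuration echo, seeds, loss traces,
#' package version) as plain JSON files.
#'
#' @param fit A [fit_w1ot()] result.
#' @param dir Target directory (created if missing).
#' @param autoencoder Optional [train_autoencoder()] model for latent-space
#'   runs.
#' @param disc Optional discriminator (kept for reproducibility; not needed
#'   for prediction).
#' @param extra Optional named list merged into the manifest.
#' @return The directory path, invisibly.
#' @export
save_checkpoint <- function(fit, dir, autoencoder = NULL, disc = NULL,
                            extra = list()) {
  stopifnot(inherits(fit, "w1ot_fit"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  .write_json(.serialize_potential(fit$map$potential),
              file.path(dir, "potential.json"))
  .write_json(.serialize_mlp(fit$map$step_size$net),
              file.path(dir, "step_size.json"))
  if (!is.null(disc)) {
    .write_json(.serialize_mlp(disc$net), file.path(dir, "discriminator.json"))
  }
  if (!is.null(autoencoder)) {
    .write_json(list(
      input_dim = autoencoder$input_dim, latent_dim = autoencoder$latent_dim,
      recon_mse = autoencoder$recon_mse,
      encoder = .serialize_mlp(autoencoder$encoder),
      decoder = .serialize_mlp(autoencoder$decoder)
    ), file.path(dir, "autoencoder.json"))
  }
  manifest <- c(list(
    package = "w1map",
    version = as.character(utils::packageVersion("w1map")),
    seed = fit$seed,
    normalize_direction = fit$map$normalize_direction,
    potential_cfg = unclass(fit$potential_cfg),
    gan_cfg = unclass(fit$gan_cfg),
    w1_estimate = fit$w1_estimate,
    potential_trace = fit$potential_trace,
    gan_trace = list(gen = unname(fit$gan_trace[, "gen"]),
                     disc = unname(fit$gan_trace[, "disc"]))
  ), extra)
  .write_json(manifest, file.path(dir, "manifest.json"))
  invisible(dir)
}

#' Load a checkpoint directory
#'
#' @param dir Directory written by [save_checkpoint()].
#' @return List with `map` (a [transport_map()]), `manifest`, and
#'   `autoencoder` (or `NULL`).
#' @export
load_checkpoint <- function(dir) {
  pot_path <- file.path(dir, "potential.json")
  if (!file.exists(pot_path)) stop("not a checkpoint directory: ", dir)
  manifest <- jsonlite::read_json(file.path(dir, "manifest.json"),
                                  simplifyVector = TRUE)
  potential <- .deserialize_potential(
    jsonlite::read_json(pot_path, simplifyVector = FALSE))
  eta <- structure(
    list(net = .deserialize_mlp(
      jsonlite::read_json(file.path(dir, "step_size.json"),
                          simplifyVector = FALSE))),
    class = "step_size_network"
  )
  ae <- NULL
  ae_path <- file.path(dir, "autoencoder.json")
  if (file.exists(ae_path)) {
    x <- jsonlite::read_json(ae_path, simplifyVector = FALSE)
    ae <- structure(list(
      encoder = .deserialize_mlp(x$encoder),
      decoder = .deserialize_mlp(x$decoder),
      input_dim = x$input_dim, latent_dim = x$latent_dim,
      recon_mse = x$recon_mse
    ), class = "autoencoder")
  }
  list(
    map = transport_map(potential, eta,
                        normalize_direction = isTRUE(manifest$normalize_direction)),
    manifest = manifest,
    autoencoder = ae
  )
}
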