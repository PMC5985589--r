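# Plain-text serialization: datasets as the long/subject CSV pair (plus
# a JSON sidecar of latent truths for simulated data) and posterior
# samples as a long-format CSV of parameter draws with a JSON meta file.

#' Write a dataset to a directory of CSV tables
#'
#' Emits `long.csv` (subject_id, marker, time, value) and
#' `subjects.csv` (subject_id, group, baseline covariates); for
#' simulated datasets carrying latent truths, a `latents.json` sidecar
#' records the true group, mixture component and random effects per
#' subject — kept out of the primary tables so fixtures stay honest.
#'
#' @param dataset a `loda_dataset`.
#' @param dir output directory (created if needed).
#' @return invisibly, the paths written.
#' @export
write_dataset <- function(dataset, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  tabs <- dataset_to_tables(dataset)
  paths <- c(long = file.path(dir, "long.csv"),
             subjects = file.path(dir, "subjects.csv"))
  utils::write.csv(tabs$long, paths[["long"]], row.names = FALSE)
  utils::write.csv(tabs$subjects, paths[["subjects"]], row.names = FALSE)
  lat <- attr(dataset, "latents")
  if (!is.null(lat) && requireNamespace("jsonlite", quietly = TRUE)) {
    paths[["latents"]] <- file.path(dir, "latents.json")
    jsonlite::write_json(lat, paths[["latents"]], auto_unbox = TRUE,
                         digits = NA)
  }
  invisible(paths)
}

#' Serialize a posterior sample to CSV + JSON meta
#'
#' One long-format CSV (`draws.csv`: iteration, parameter, value) using
#' the same parameter naming as [posterior_summary()] (without
#' relabeling), plus `meta.json` with the sampler settings.
#'
#' @param sample a `loda_posterior`.
#' @param dir output directory.
#' @return invisibly, the paths written.
#' @export
write_posterior <- function(sample, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  mat <- t(vapply(sample$draws, .flatten_draw, relabel = FALSE,
                  .flatten_draw(sample$draws[[1L]], FALSE)))
  long <- data.frame(
    iteration = rep(seq_len(nrow(mat)), times = ncol(mat)),
    parameter = rep(colnames(mat), each = nrow(mat)),
    value = as.vector(mat))
  paths <- c(draws = file.path(dir, "draws.csv"),
             meta = file.path(dir, "meta.json"))
  utils::write.csv(long, paths[["draws"]], row.names = FALSE)
  if (requireNamespace("jsonlite", quietly = TRUE))
    jsonlite::write_json(sample$meta, paths[["meta"]], auto_unbox = TRUE,
                         digits = NA, force = TRUE)
  invisible(paths)
}

#' Read back a serialized posterior sample
#'
#' Reconstructs the draw list from the [write_posterior()] layout.  The
#' group spec is not serialized and must be supplied to rebuild the
#' parameter structure.
#'
#' @param dir directory written by [write_posterior()].
#' @param spec the [group_model_spec()] the sample was fitted under.
#' @return a `loda_posterior`.
#' @export
read_posterior <- function(dir, spec) {
  long <- utils::read.csv(file.path(dir, "draws.csv"))
  lay <- .ranef_layout(spec)
  q <- lay$q
  K <- spec$K
  iters <- sort(unique(long$iteration))
  wide <- split(long, long$iteration)
  draws <- lapply(iters, function(it) {
    row <- stats::setNames(wide[[as.character(it)]]$value,
                           wide[[as.character(it)]]$parameter)
    alpha <- list(); phi <- c()
    for (nm in names(spec$markers)) {
      p <- length(spec$markers[[nm]]$fixed)
      alpha[[nm]] <- if (p) unname(row[paste0("alpha_", nm, "[", 1:p, "]")])
        else numeric(0)
      phi[[nm]] <- unname(row[paste0("phi_", nm)])
    }
    w <- unname(row[paste0("w[", 1:K, "]")])
    mu <- lapply(1:K, function(k)
      unname(row[paste0("mu[", k, "][", 1:q, "]")]))
    D <- lapply(1:K, function(k) {
      M <- matrix(0, q, q)
      for (a in 1:q) for (b in a:q)
        M[a, b] <- M[b, a] <- row[[paste0("D[", k, "][", a, ",", b, "]")]]
      M
    })
    list(psi = list(alpha = alpha, phi = phi),
         theta = list(w = w, mu = mu, D = D))
  })
  meta <- list(M = length(draws), group = spec$group, K = K, q = q)
  mp <- file.path(dir, "meta.json")
  if (file.exists(mp) && requireNamespace("jsonlite", quietly = TRUE))
    meta <- utils::modifyList(jsonlite::read_json(mp, simplifyVector = TRUE),
                              list(M = length(draws)))
  structure(list(draws = draws, meta = meta, spec = spec),
            class = "loda_posterior")
}
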