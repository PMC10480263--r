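#' Derive a stage seed from a global seed
#'
#' All stochastic stages draw their seeds deterministically from one
#' global seed plus a fixed per-stage offset, so a single integer
#' reproduces an entire run. The result always lies in `[1, 2^31 - 2]`.
#'
#' @param global_seed integer global seed.
#' @param stage character stage name (e.g. `"phantom"`, `"simulate"`,
#'   `"train"`, `"transfer"`, `"split"`).
#' @param index integer sub-index within the stage (patient, slice, ...).
#' @return integer seed.
#' @export
derive_seed <- function(global_seed, stage, index = 0L) {
  offsets <- c(phantom = 11L, simulate = 23L, train = 37L, transfer = 53L,
               split = 71L, deform = 83L, mix = 97L, isocentre = 113L,
               init = 127L, eval = 139L, cli = 151L)
  off <- offsets[[stage]]
  if (is.null(off)) off <- 997L
  s <- (as.double(global_seed) %% 46337) * 46337 +
    as.double(off) * 131 + as.double(index)
  as.integer(s %% 2147483645) + 1L
}

run_config_sections <- c("phantom", "sim", "prep", "train", "transfer",
                         "eval", "seed", "out_dir", "profile")

#' Read a run configuration file
#'
#' Configurations are YAML documents with sections mirroring the
#' pipeline stages (`phantom`, `sim`, `prep`, `train`, `transfer`,
#' `eval`) plus a global `seed`, an `out_dir` and a scale `profile`
#' (`"desk"` or `"paper"`). Unknown top-level keys are rejected rather
#' than silently ignored.
#'
#' @param path path to a YAML file.
#' @return named list of configuration sections.
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  unknown <- setdiff(names(cfg), run_config_sections)
  if (length(unknown))
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "))
  cfg$seed <- if (is.null(cfg$seed)) 1L else as.integer(cfg$seed)
  if (is.null(cfg$profile)) cfg$profile <- "desk"
  cfg
}

#' @rdname read_run_config
#' @param cfg configuration list.
#' @export
write_run_config <- function(cfg, path) {
  unknown <- setdiff(names(cfg), run_config_sections)
  if (length(unknown))
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "))
  yaml::write_yaml(cfg, path)
  invisible(path)
}

write_manifest <- function(manifest, path) {
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

fingerprint <- function(x) {
  # stable content hash of any R object (used for data-hygiene manifests)
  f <- tempfile()
  on.exit(unlink(f))
  con <- file(f, "wb")
  serialize(x, con, version = 2, xdr = TRUE)
  close(con)
  unname(tools::md5sum(f))
}
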