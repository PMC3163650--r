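#' Read and write a generator configuration as YAML
#'
#' One structured file controls all synthetic-data generators. The schema
#' is flat: every scalar/vector argument of [synth_config()] under its own
#' key, `qpcr_groups` as a list of `{group, n}` records, and
#' `behavior_effect` as a mapping `endpoint -> {genotype: shift}`. Keys not
#' present fall back to the defaults of [synth_config()]; unknown keys are
#' an error.
#'
#' @param path YAML file path.
#' @param cfg A [synth_config()].
#' @return `read_synth_config()` returns a [synth_config()];
#'   `write_synth_config()` returns `path` invisibly.
#' @export
read_synth_config <- function(path) {
  raw <- yaml::read_yaml(path)
  known <- names(formals(synth_config))
  unknown <- setdiff(names(raw), known)
  if (length(unknown) > 0) {
    abort(paste("unknown configuration key(s):", paste(unknown, collapse = ", ")))
  }
  if (!is.null(raw$qpcr_groups)) {
    raw$qpcr_groups <- dplyr::bind_rows(lapply(raw$qpcr_groups, tibble::as_tibble))
  }
  if (!is.null(raw$behavior_effect)) {
    raw$behavior_effect <- lapply(raw$behavior_effect, unlist)
  }
  do.call(synth_config, raw)
}

#' @rdname read_synth_config
#' @export
write_synth_config <- function(cfg, path) {
  stopifnot(inherits(cfg, "synth_config"))
  out <- unclass(cfg)
  out$qpcr_groups <- lapply(seq_len(nrow(cfg$qpcr_groups)), function(i) {
    list(group = cfg$qpcr_groups$group[i], n = cfg$qpcr_groups$n[i])
  })
  out$behavior_effect <- lapply(cfg$behavior_effect, as.list)
  yaml::write_yaml(out, path)
  invisible(path)
}
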