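#' Read a cross configuration from YAML
#'
#' The file holds flat keys (`seed`, cohort sizes, `n_f1_pairs`,
#' `error_model`) plus a `layout` entry — `"default"`, a path to a marker
#' map TSV (resolved relative to the config file), or an inline list of
#' records — and a `regimes` list whose entries are either
#' `{preset: name}` or a full regime (`stage`, `single_locus`,
#' `epistatic_pairs`). The schema is validated before anything is
#' simulated.
#'
#' @param path Path to a YAML file.
#' @return A validated [cross_config()].
#' @export
read_cross_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  y <- yaml::read_yaml(path)
  layout <- y$layout
  if (is.null(layout) || identical(layout, "default")) {
    layout <- default_genome_layout()
  } else if (is.character(layout) && length(layout) == 1L) {
    map_path <- if (file.exists(layout)) layout else
      file.path(dirname(path), layout)
    layout <- read_marker_map(map_path)
  } else {
    layout <- do.call(rbind, lapply(layout, function(rec) {
      data.frame(name = rec$name, chromosome = rec$chromosome,
                 position_cM = rec$position_cM,
                 marker_class = rec$marker_class %||% "snp")
    }))
  }
  regimes <- lapply(y$regimes %||% list(), function(reg) {
    if (!is.null(reg$preset)) {
      pre <- regime_preset(reg$preset, layout)
      if (!length(pre)) return(NULL)
      return(pre[[1L]])
    }
    pairs <- lapply(reg$epistatic_pairs %||% list(), function(pr) {
      list(markers = unlist(pr$markers),
           table = matrix(unlist(pr$table), 3L, 3L, byrow = TRUE))
    })
    selection_regime(
      single_locus = lapply(reg$single_locus %||% list(), unlist),
      epistatic_pairs = pairs,
      stage = reg$stage %||% "hatching_to_adult")
  })
  regimes <- Filter(Negate(is.null), regimes)
  em <- y$error_model %||% list()
  pairs <- y$n_f1_pairs %||% list()
  cross_config(
    layout = layout, regimes = regimes,
    n_nauplii = y$n_nauplii %||% 190L,
    n_adult_males = y$n_adult_males %||% 205L,
    n_nrbc_males = y$n_nrbc_males %||% 39L,
    n_f1_pairs = c(nauplii = pairs$nauplii %||% 4L,
                   adult = pairs$adult %||% 25L,
                   nrbc = pairs$nrbc %||% 7L),
    error_model = error_model(em$het_undercall_rate %||% 0.02,
                              em$missing_rate %||% 0.02),
    seed = y$seed %||% 1L)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Digest of a cross configuration
#'
#' MD5 digest of the canonical YAML serialization, recorded in run
#' metadata so a result set can be traced to the exact configuration.
#'
#' @param config A [cross_config()].
#' @return Character scalar (32 hex digits).
#' @export
config_digest <- function(config) {
  f <- tempfile(fileext = ".yaml")
  on.exit(unlink(f))
  plain <- list(layout = lapply(config$layout, as.vector),
                regimes = rapply(config$regimes, as.vector, how = "list"),
                n_nauplii = config$n_nauplii,
                n_adult_males = config$n_adult_males,
                n_nrbc_males = config$n_nrbc_males,
                n_f1_pairs = as.list(config$n_f1_pairs),
                error_model = unclass(config$error_model),
                seed = config$seed)
  yaml::write_yaml(plain, f)
  unname(tools::md5sum(f))
}
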