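#' Pipeline configuration
#'
#' Bundle of the thresholds used across the pipeline.  Defaults equal the
#' published analysis settings: features must be detected in 90% of samples
#' to pass the presence filter, differential expression requires an adjusted
#' global p below 0.05 together with a pairwise fold change above 1.5, three
#' subtypes are cut from the sample dendrogram, the 20 most central network
#' nodes seed candidate selection, EAGLE runs with clique-size threshold 3
#' and complex-size threshold 2, and the count filter drops features with
#' fewer than 10 counts in more than 90% of samples.
#'
#' @param presence_fraction minimum fraction of samples in which a feature
#'   must be detected (inclusive), in (0, 1].
#' @param de_p_threshold significance threshold for differential expression.
#' @param fold_change_threshold minimum pairwise fold change (linear ratio).
#' @param n_subtypes number of flat clusters cut from the sample dendrogram.
#' @param top_central number of top-ranked central nodes used in candidate
#'   selection.
#' @param clique_size_threshold minimal maximal-clique size seeding an EAGLE
#'   community.
#' @param complex_size_threshold minimal size of a reported community.
#' @param min_count count-filter threshold (counts below this are "low").
#' @param max_low_fraction a feature is dropped when low in strictly more
#'   than this fraction of samples.
#' @param interaction_p_threshold permutation-p threshold for retaining an
#'   inferred miR-gene interaction.
#' @param pca_sd_multiplier outlier rule: flag samples farther than
#'   mean + k*sd from the PCA-score centroid.
#' @param use_adjusted_global logical; apply the DE p threshold to the
#'   BH-adjusted global p (default) rather than the raw p.
#' @param rng_seed integer seed recorded in run manifests.
#' @return A validated list of class `crcmir_config`.
#' @export
pipeline_config <- function(presence_fraction = 0.90,
                            de_p_threshold = 0.05,
                            fold_change_threshold = 1.5,
                            n_subtypes = 3L,
                            top_central = 20L,
                            clique_size_threshold = 3L,
                            complex_size_threshold = 2L,
                            min_count = 10,
                            max_low_fraction = 0.90,
                            interaction_p_threshold = 0.05,
                            pca_sd_multiplier = 3,
                            use_adjusted_global = TRUE,
                            rng_seed = 1L) {
  cfg <- list(
    presence_fraction = presence_fraction,
    de_p_threshold = de_p_threshold,
    fold_change_threshold = fold_change_threshold,
    n_subtypes = as.integer(n_subtypes),
    top_central = as.integer(top_central),
    clique_size_threshold = as.integer(clique_size_threshold),
    complex_size_threshold = as.integer(complex_size_threshold),
    min_count = min_count,
    max_low_fraction = max_low_fraction,
    interaction_p_threshold = interaction_p_threshold,
    pca_sd_multiplier = pca_sd_multiplier,
    use_adjusted_global = isTRUE(use_adjusted_global),
    rng_seed = as.integer(rng_seed)
  )
  validate_config(cfg)
  class(cfg) <- "crcmir_config"
  cfg
}

validate_config <- function(cfg) {
  prop <- function(name) {
    v <- cfg[[name]]
    if (!is.numeric(v) || length(v) != 1 || is.na(v) || v <= 0 || v > 1)
      stopf("config field '%s' must be a proportion in (0, 1], got %s",
            name, format(cfg[[name]]))
  }
  prop("presence_fraction")
  prop("de_p_threshold")
  prop("max_low_fraction")
  prop("interaction_p_threshold")
  pos <- function(name) {
    v <- cfg[[name]]
    if (!is.numeric(v) || length(v) != 1 || is.na(v) || v <= 0)
      stopf("config field '%s' must be > 0", name)
  }
  pos("fold_change_threshold")
  pos("min_count")
  pos("pca_sd_multiplier")
  cnt <- function(name) {
    v <- cfg[[name]]
    if (!is.numeric(v) || length(v) != 1 || is.na(v) || v < 1 || v != round(v))
      stopf("config field '%s' must be a count >= 1", name)
  }
  cnt("n_subtypes")
  cnt("top_central")
  cnt("clique_size_threshold")
  cnt("complex_size_threshold")
  invisible(cfg)
}

#' Read / write a pipeline configuration
#'
#' Configurations are stored as a flat JSON document of key:value pairs;
#' unknown keys are rejected and out-of-range values raise an error.
#'
#' @param path file path of a JSON config document.
#' @rdname config_io
#' @return `read_config()` a `crcmir_config`; `write_config()` `path`,
#'   invisibly.
#' @export
read_config <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  known <- names(formals(pipeline_config))
  unknown <- setdiff(names(raw), known)
  if (length(unknown) > 0)
    stopf("unknown config key(s): %s", paste(unknown, collapse = ", "))
  do.call(pipeline_config, raw)
}

#' @param config a `crcmir_config`.
#' @rdname config_io
#' @export
write_config <- function(config, path) {
  validate_config(config)
  jsonlite::write_json(unclass(config), path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}
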