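# Pipeline plumbing: one configuration object drives
# enumerate -> classify -> simulate (or ingest) -> label -> aggregate ->
# attribute, with every artifact written as TSV/JSON plus a manifest of
# checksums so runs are auditable and byte-reproducible.

#' Write / read the package's tab-separated interchange format
#'
#' TSV with a header row, tab delimiter and '.' decimal mark.
#'
#' @param x data.frame to write.
#' @param path file path.
#' @return the path (write) or a data.frame (read).
#' @export
g4_write_tsv <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     dec = ".", fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname g4_write_tsv
#' @export
g4_read_tsv <- function(path) {
  utils::read.delim(path, sep = "\t", dec = ".", stringsAsFactors = FALSE,
                    check.names = FALSE)
}

#' Pipeline configuration
#'
#' @param n_tetrads 2 or 3.
#' @param helicity \code{"RH"} or \code{"LH"}.
#' @param loop_length_range admissible per-loop lengths (default 1:4).
#' @param rules a \code{g4_rules} object.
#' @param thresholds a \code{g4_thresholds} object.
#' @param sim_params a \code{g4_sim_params} object.
#' @param seed integer seed for the simulate and attribute stages.
#' @param ingest optional path to a TSV of records (grid columns +
#'   \code{rmsd_nm}); when given the simulate stage is skipped.
#' @param classifier list of classifier settings (\code{folds},
#'   \code{nrounds}).
#' @param attribution list of attribution settings (\code{nrounds},
#'   \code{max_records}: records are subsampled beyond this for the
#'   retrain-per-coalition Shapley stage).
#' @return object of class \code{g4_config}.
#' @export
g4_pipeline_config <- function(n_tetrads = 3, helicity = "RH",
                               loop_length_range = 1:4,
                               rules = g4_rules(),
                               thresholds = default_thresholds(),
                               sim_params = g4_sim_params(),
                               seed = 1, ingest = NULL,
                               classifier = list(folds = 10, nrounds = 50),
                               attribution = list(nrounds = 20,
                                                  max_records = 4000)) {
  structure(
    list(n_tetrads = n_tetrads, helicity = helicity,
         loop_length_range = loop_length_range, rules = rules,
         thresholds = thresholds, sim_params = sim_params, seed = seed,
         ingest = ingest, classifier = classifier,
         attribution = attribution),
    class = "g4_config"
  )
}

#' @rdname g4_pipeline_config
#' @param config a \code{g4_config} object.
#' @param path optional file path.
#' @export
config_to_json <- function(config, path = NULL) {
  stopifnot(inherits(config, "g4_config"))
  x <- unclass(config)
  x$rules <- unclass(x$rules)
  x$sim_params <- unclass(x$sim_params)
  x$thresholds <- list(thresholds = as.list(x$thresholds$thresholds),
                       percentile = x$thresholds$percentile)
  js <- jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA, null = "null")
  if (is.null(path)) return(js)
  writeLines(js, path)
  invisible(path)
}

#' @rdname g4_pipeline_config
#' @param json JSON string or file path.
#' @export
config_from_json <- function(json) {
  x <- jsonlite::fromJSON(json)
  x$rules <- do.call(g4_rules, as.list(x$rules))
  x$thresholds <- g4_thresholds(unlist(x$thresholds$thresholds),
                                x$thresholds$percentile)
  x$sim_params <- do.call(g4_sim_params, as.list(x$sim_params))
  x$classifier <- as.list(x$classifier)
  x$attribution <- as.list(x$attribution)
  do.call(g4_pipeline_config, x)
}

run_stage <- function(manifest, name, skipped = FALSE, note = "") {
  manifest$stages[[length(manifest$stages) + 1L]] <-
    list(stage = name, skipped = skipped, note = note)
  manifest
}

#' Run the full analysis pipeline
#'
#' Stages: \code{enumerate} the conformational grid, \code{classify}
#' propeller geometry (census), \code{simulate} synthetic records (or
#' ingest a TSV), \code{label} by RMSD thresholding, \code{aggregate}
#' foldability maps and feature tables, and \code{attribute} (classifier
#' CV precision + exact Shapley). Writes TSV/JSON artifacts and a manifest
#' with checksums to \code{out_dir}.
#'
#' @param config a \code{g4_config} object.
#' @param out_dir output directory (created if missing).
#' @return list with the artifacts (invisibly also written to disk) and
#'   the manifest.
#' @export
run_pipeline <- function(config, out_dir) {
  stopifnot(inherits(config, "g4_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(package = "g4topo",
                   version = as.character(utils::packageVersion("g4topo")),
                   r_version = as.character(getRversion()),
                   seed = config$seed,
                   config_hash = unname(substr(digest_json(config), 1, 32)),
                   stages = list(), files = list())
  out <- list()

  stage <- function(name, expr) {
    res <- tryCatch(expr, error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
    res
  }

  # enumerate
  grid <- stage("enumerate", enumerate_conformations(
    config$n_tetrads, config$loop_length_range, config$helicity))
  g4_write_tsv(grid, file.path(out_dir, "conformations.tsv"))
  manifest <- run_stage(manifest, "enumerate",
                        note = paste(nrow(grid), "conformations"))

  # classify
  census <- stage("classify", propeller_census(config$helicity))
  g4_write_tsv(census, file.path(out_dir, "census.tsv"))
  manifest <- run_stage(manifest, "classify",
                        note = paste(sum(census$has_ld), "LD-bearing"))

  # simulate or ingest
  if (is.null(config$ingest)) {
    records <- stage("simulate", generate_records(grid, config$sim_params,
                                                  seed = config$seed))
    manifest <- run_stage(manifest, "simulate",
                          note = paste(nrow(records), "records"))
  } else {
    records <- stage("simulate", {
      r <- g4_read_tsv(config$ingest)
      need <- c("conformation_id", "n_tetrads", "helicity", "topology",
                "polarity", "len_I", "len_II", "len_III", "rmsd_nm")
      miss <- setdiff(need, names(r))
      if (length(miss) > 0L) stop("ingest TSV lacks column(s): ",
                                  paste(miss, collapse = ", "))
      r
    })
    manifest <- run_stage(manifest, "simulate", skipped = TRUE,
                          note = paste("ingested", config$ingest))
  }
  g4_write_tsv(records, file.path(out_dir, "records.tsv"))

  # label
  records <- stage("label", label_foldable(records, config$thresholds))
  g4_write_tsv(records, file.path(out_dir, "records_labeled.tsv"))
  manifest <- run_stage(manifest, "label",
                        note = sprintf("%.1f%% foldable",
                                       100 * mean(records$foldable)))

  # aggregate
  agg <- stage("aggregate", {
    fmap <- foldability_map(records)
    list(
      map = data.frame(topology = rownames(fmap), fmap,
                       check.names = FALSE, stringsAsFactors = FALSE),
      by_type = foldability_by_feature(records, "type"),
      by_length = foldability_by_feature(records, "length"),
      pairs = two_loop_combination_table(records)
    )
  })
  g4_write_tsv(agg$map, file.path(out_dir, "foldability_map.tsv"))
  g4_write_tsv(agg$by_type, file.path(out_dir, "foldability_by_type.tsv"))
  g4_write_tsv(agg$by_length, file.path(out_dir, "foldability_by_length.tsv"))
  g4_write_tsv(agg$pairs, file.path(out_dir, "two_loop_combinations.tsv"))
  manifest <- run_stage(manifest, "aggregate")

  # attribute
  attribution <- stage("attribute", {
    clf <- fit_foldability_classifier(records,
                                      folds = config$classifier$folds,
                                      seed = config$seed,
                                      nrounds = config$classifier$nrounds)
    sub <- records
    if (nrow(sub) > config$attribution$max_records) {
      set.seed(config$seed)
      sub <- sub[sort(sample.int(nrow(sub),
                                 config$attribution$max_records)), ,
                 drop = FALSE]
    }
    shap <- exact_shapley_attribution(sub, seed = config$seed,
                                      nrounds = config$attribution$nrounds)
    list(precision = clf$precision, prevalence = clf$prevalence,
         per_feature = shap$per_feature, per_value = shap$per_value)
  })
  jsonlite::write_json(
    list(precision = attribution$precision,
         prevalence = attribution$prevalence,
         per_feature = as.list(attribution$per_feature)),
    file.path(out_dir, "attribution.json"), auto_unbox = TRUE, digits = NA)
  g4_write_tsv(attribution$per_value,
               file.path(out_dir, "attribution_values.tsv"))
  manifest <- run_stage(manifest, "attribute",
                        note = sprintf("CV precision %.3f",
                                       attribution$precision))

  files <- list.files(out_dir, full.names = TRUE)
  files <- files[!basename(files) %in% "manifest.json"]
  manifest$files <- lapply(files, function(f) {
    list(file = basename(f), md5 = unname(tools::md5sum(f)))
  })
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(list(grid = grid, census = census, records = records,
                 aggregate = agg, attribution = attribution,
                 manifest = manifest, out_dir = out_dir))
}

digest_json <- function(config) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  writeLines(config_to_json(config), tmp)
  tools::md5sum(tmp)
}

#' Human-readable summary of a pipeline run
#'
#' @param out_dir directory written by [run_pipeline()].
#' @return character vector of summary lines, invisibly; printed.
#' @export
report_census <- function(out_dir) {
  manifest_path <- file.path(out_dir, "manifest.json")
  if (!file.exists(manifest_path)) {
    stop("no manifest.json in ", out_dir, "; run the pipeline first")
  }
  census <- g4_read_tsv(file.path(out_dir, "census.tsv"))
  records <- g4_read_tsv(file.path(out_dir, "records_labeled.tsv"))
  records$foldable <- as.logical(records$foldable)
  by_topo <- tapply(records$foldable, records$topology, mean)
  lines <- c(
    sprintf("Topologies: %d total, %d with long-distance propellers, %d without",
            nrow(census), sum(census$has_ld), sum(!census$has_ld)),
    sprintf("Zero-LD set includes -pd+p: %s",
            "-pd+p" %in% census$topology[!census$has_ld]),
    sprintf("Records: %d; foldable fraction %.3f", nrow(records),
            mean(records$foldable)),
    sprintf("Most foldable topology: %s (%.3f); least: %s (%.3f)",
            names(by_topo)[which.max(by_topo)], max(by_topo),
            names(by_topo)[which.min(by_topo)], min(by_topo))
  )
  cat(lines, sep = "\n")
  invisible(lines)
}
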