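#' Validate a benchmark configuration file
#'
#' JSON configuration with two blocks: `genome` (path to a chrom.sizes file),
#' `datasets` (list of `{label, peaks, dialect, fragments?, role}` with role
#' one of `candidate`, `reference-replicate`, `control`) and an optional
#' `analysis` block (`window_size`, `ref_fdr`, `maxgap`, `n_quantiles`,
#' `bin_size`, `flank`, `body_bins`, `flank_bin`, `seed`).  Unknown keys,
#' duplicate labels, missing files and role conflicts are all rejected with
#' actionable messages; every defaulted value is reported via `message()`.
#'
#' @param path JSON file.
#' @return a validated config list of class `benchmark_config`.
#' @export
validate_config <- function(path) {
  if (!file.exists(path)) stop("validate_config: no such file: ", path)
  cfg <- jsonlite::fromJSON(path, simplifyDataFrame = FALSE)
  allowed_top <- c("genome", "datasets", "analysis")
  unknown <- setdiff(names(cfg), allowed_top)
  if (length(unknown)) {
    stop("validate_config: unknown key(s): ", paste(unknown, collapse = ", "))
  }
  if (is.null(cfg$genome)) stop("validate_config: 'genome' is required")
  if (!file.exists(cfg$genome)) {
    stop("validate_config: genome file not found: ", cfg$genome)
  }
  if (is.null(cfg$datasets) || length(cfg$datasets) == 0) {
    stop("validate_config: 'datasets' is required")
  }
  allowed_ds <- c("label", "peaks", "dialect", "fragments", "role")
  roles <- character(0); labels <- character(0)
  for (d in cfg$datasets) {
    unknown <- setdiff(names(d), allowed_ds)
    if (length(unknown)) {
      stop("validate_config: dataset '", d$label %||% "?",
           "': unknown key(s): ", paste(unknown, collapse = ", "))
    }
    for (k in c("label", "peaks", "role")) {
      if (is.null(d[[k]])) {
        stop("validate_config: dataset missing required key '", k, "'")
      }
    }
    if (!d$role %in% c("candidate", "reference-replicate", "control")) {
      stop("validate_config: dataset '", d$label, "': bad role '", d$role,
           "' (candidate / reference-replicate / control)")
    }
    if (!file.exists(d$peaks)) {
      stop("validate_config: dataset '", d$label, "': peaks file not found: ",
           d$peaks)
    }
    if (!is.null(d$fragments) && !file.exists(d$fragments)) {
      stop("validate_config: dataset '", d$label,
           "': fragments file not found: ", d$fragments)
    }
    labels <- c(labels, d$label)
    roles <- c(roles, d$role)
  }
  if (anyDuplicated(labels)) {
    stop("validate_config: duplicate dataset label(s): ",
         paste(unique(labels[duplicated(labels)]), collapse = ", "))
  }
  if (sum(roles == "candidate") < 1) {
    stop("validate_config: need >= 1 dataset with role 'candidate'")
  }
  if (sum(roles == "reference-replicate") < 1) {
    stop("validate_config: need >= 1 dataset with role 'reference-replicate'")
  }
  defaults <- list(window_size = 5000, ref_fdr = 0.05, maxgap = 0,
                   n_quantiles = 10, bin_size = 2000, flank = 1000,
                   body_bins = 100, flank_bin = 20, seed = 1)
  an <- cfg$analysis %||% list()
  unknown <- setdiff(names(an), names(defaults))
  if (length(unknown)) {
    stop("validate_config: unknown analysis key(s): ",
         paste(unknown, collapse = ", "))
  }
  for (k in names(defaults)) {
    if (is.null(an[[k]])) {
      an[[k]] <- defaults[[k]]
      message("validate_config: defaulting analysis$", k, " = ",
              defaults[[k]])
    }
  }
  for (i in seq_along(cfg$datasets)) {
    if (is.null(cfg$datasets[[i]]$dialect)) {
      cfg$datasets[[i]]$dialect <- "narrowPeak"
      message("validate_config: defaulting dialect = narrowPeak for '",
              cfg$datasets[[i]]$label, "'")
    }
  }
  structure(list(genome = cfg$genome, datasets = cfg$datasets,
                 analysis = an), class = "benchmark_config")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run the full benchmark battery
#'
#' Composes the evaluation stages on the configured datasets: a consensus
#' reference from the reference replicates at `ref_fdr` (single replicate:
#' its peaks at `ref_fdr`), per-candidate ROC/PRC curves, the Jaccard
#' similarity matrix and clusterogram over all datasets, per-candidate
#' maxgap overlap reports and FDR-quantile recovery, and a manifest with
#' package version, seed and input checksums.  Inputs are never mutated; the
#' report directory is the only side effect, and a rerun with identical
#' inputs and seed reproduces every TSV byte-identically.
#'
#' @param cfg a [validate_config()] result.
#' @param out_dir report directory (created if absent).
#' @return invisibly, `out_dir`.
#' @export
run_benchmark <- function(cfg, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  an <- cfg$analysis
  sizes <- read_chrom_sizes(cfg$genome)
  w <- an$window_size

  ds <- lapply(cfg$datasets, function(d) {
    d$pk <- read_peaks(d$peaks, d$dialect, sizes)
    d
  })
  labels <- vapply(ds, `[[`, character(1), "label")
  roles <- vapply(ds, `[[`, character(1), "role")

  message("run_benchmark: building reference from ",
          sum(roles == "reference-replicate"), " replicate(s) at ",
          an$ref_fdr * 100, "% FDR")
  refs <- ds[roles == "reference-replicate"]
  ref_pk <- if (length(refs) >= 2) {
    merge_replicates(refs[[1]]$pk, refs[[2]]$pk, fdr_cutoff = an$ref_fdr,
                     maxgap = an$maxgap)
  } else {
    pk <- refs[[1]]$pk
    pk[pk$q >= -log10(an$ref_fdr), , drop = FALSE]
  }
  if (nrow(ref_pk) == 0) stop("run_benchmark: reference set is empty")
  write_peaks(ref_pk, file.path(out_dir, "reference_peaks.narrowPeak"))
  ref_ws <- peaks_to_windows(ref_pk, w, sizes)

  curves <- list()
  for (d in ds[roles == "candidate"]) {
    message("run_benchmark: ROC/PRC vs consensus reference for '", d$label,
            "' (replicated-reference window ROC analogue)")
    sw <- score_windows(d$pk, w, sizes)
    ec <- roc_prc(ref_ws, sw, sizes)
    write_curve(ec, file.path(out_dir, paste0("curve_", d$label, ".tsv")))
    curves[[d$label]] <- ec
  }

  message("run_benchmark: Jaccard similarity and clusterogram over ",
          length(ds), " datasets")
  sets <- lapply(ds, function(d) {
    peaks_to_windows(d$pk, w, sizes, fdr_cutoff = an$ref_fdr)
  })
  S <- similarity_matrix(sets, labels)
  write_similarity(S, file.path(out_dir, "jaccard_matrix.tsv"))
  dend <- cluster_similarity(S)
  write_dendrogram(dend, file.path(out_dir, "dendrogram.tsv"))

  ov_rows <- list(); qr_rows <- list()
  for (d in ds[roles == "candidate"]) {
    message("run_benchmark: overlap report and FDR-quantile recovery for '",
            d$label, "' (maxgap ", an$maxgap, ")")
    ov <- find_overlaps(d$pk, ref_pk, maxgap = an$maxgap)
    ov_rows[[d$label]] <- data.frame(
      label = d$label, maxgap = ov$maxgap, nA = ov$nA, nB = ov$nB,
      nA_hit = ov$nA_hit, nB_hit = ov$nB_hit,
      components_both = ov$components[["both"]],
      components_onlyA = ov$components[["onlyA"]],
      components_onlyB = ov$components[["onlyB"]],
      pctA = ov$pctA, pctB = ov$pctB, pct_venn = ov$pct_venn,
      stringsAsFactors = FALSE)
    if (any(d$pk$q != -1)) {
      qr <- fdr_quantile_recovery(d$pk, ref_pk, maxgap = an$maxgap,
                                  n_quantiles = an$n_quantiles)
      qr$label <- d$label
      qr_rows[[d$label]] <- as.data.frame(qr)
    }
  }
  write_tsv(do.call(rbind, ov_rows), file.path(out_dir, "overlaps.tsv"))
  if (length(qr_rows)) {
    write_tsv(do.call(rbind, qr_rows),
              file.path(out_dir, "quantile_recovery.tsv"))
  }

  inputs <- c(cfg$genome, vapply(cfg$datasets, `[[`, character(1), "peaks"))
  manifest <- list(package = "peakbench",
                   version = as.character(utils::packageVersion("peakbench")),
                   seed = an$seed,
                   analysis = an,
                   inputs = as.list(setNames(unname(tools::md5sum(inputs)),
                                             inputs)))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(out_dir)
}
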