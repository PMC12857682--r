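#' Read and validate a plate-layout table
#'
#' Reads a CSV layout with headers `plate`, `well`, `gene`, `sirna_id`,
#' `condition`, `replicate`. Well identifiers are normalized to
#' letter + two-digit form (`a1` -> `A01`); duplicate plate/well/replicate
#' combinations and unknown condition tokens are rejected with the
#' offending row named.
#'
#' @param path CSV file path.
#' @param conditions allowed condition tokens.
#' @return validated layout data frame.
#' @export
read_layout <- function(path, conditions = c("assay", "control", "empty")) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  required <- c("plate", "well", "gene", "sirna_id", "condition", "replicate")
  missing <- setdiff(required, names(df))
  if (length(missing) > 0)
    stop("layout ", path, " is missing required header(s): ",
         paste(missing, collapse = ", "))
  df$well <- normalize_well(df$well)
  bad <- which(!(df$condition %in% conditions))
  if (length(bad) > 0)
    stop("unknown condition token '", df$condition[bad[1]], "' in layout row ",
         bad[1])
  key <- paste(df$plate, df$well, df$replicate)
  dup <- which(duplicated(key))
  if (length(dup) > 0)
    stop("duplicate plate+well in layout row ", dup[1], " (plate ",
         df$plate[dup[1]], ", well ", df$well[dup[1]], ")")
  df
}

#' Normalize well identifiers to letter + two-digit form
#'
#' @param well character vector like `"a1"`, `"A01"`, `"P24"`.
#' @return normalized identifiers, e.g. `"A01"`.
#' @export
normalize_well <- function(well) {
  m <- regmatches(well, regexec("^([A-Za-z]+)0*([0-9]+)$", well))
  bad <- which(vapply(m, length, integer(1)) != 3L)
  if (length(bad) > 0)
    stop("malformed well identifier '", well[bad[1]], "'")
  vapply(m, function(p) sprintf("%s%02d", toupper(p[2]), as.integer(p[3])),
         character(1))
}

#' Load a multi-channel field from TIFF files
#'
#' Reads one TIFF per channel. Multi-page TIFFs are treated as z-stacks:
#' with `projection = "max"` the pixelwise maximum across planes is taken;
#' with `"none"` a stack is an error. All channels must share one shape.
#' Intensities are returned on their stored scale (16-bit files map to
#' 0..65535).
#'
#' @param paths named character vector of TIFF paths (names become channel
#'   names).
#' @param projection `"none"` or `"max"`.
#' @return named list of numeric matrices.
#' @export
load_field <- function(paths, projection = c("none", "max")) {
  projection <- match.arg(projection)
  chans <- lapply(paths, function(p) {
    pages <- tiff::readTIFF(p, all = TRUE, as.is = FALSE)
    mats <- lapply(pages, function(pl) {
      m <- as.matrix(pl)
      if (length(dim(pl)) == 3) m <- pl[, , 1]   # first sample of multi-sample
      m * 65535
    })
    if (length(mats) == 1) return(mats[[1]])
    if (projection == "none")
      stop("multi-page TIFF ", p, " needs projection = \"max\"")
    Reduce(pmax, mats)
  })
  shapes <- vapply(chans, function(m) paste(dim(m), collapse = "x"), character(1))
  if (length(unique(shapes)) > 1)
    stop("channel shapes differ: ", paste(shapes, collapse = ", "))
  chans
}

#' Write a raster as a 16-bit grayscale TIFF
#'
#' @param raster numeric matrix; values are clamped to 0..65535.
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_field_tiff <- function(raster, path) {
  x <- pmin(pmax(raster, 0), 65535) / 65535
  tiff::writeTIFF(x, path, bits.per.sample = 16)
  invisible(path)
}

#' Run the table-level screen pipeline end to end
#'
#' Simulates (or accepts) well-level screen tables, applies plate z-score
#' normalization per replicate, calls primary hits, and compares calls to
#' the planted truth. When `out_dir` is given, all tables are written as
#' CSV together with a JSON manifest recording the configuration, seed,
#' thresholds, and an MD5 checksum per output file. Re-running with the
#' same configuration reproduces the outputs byte for byte.
#'
#' @param config a [screen_sim_config()].
#' @param thresholds a [screen_thresholds()].
#' @param min_nuclei well-retention threshold (see [retain_wells()]).
#' @param out_dir optional output directory.
#' @return list with `wells` (z-scored, retained), `dropped`, `z_table`
#'   (per gene), `hits`, `truth`, `confusion` (truth class x called
#'   class), and `manifest`.
#' @export
run_pipeline <- function(config = screen_sim_config(),
                         thresholds = screen_thresholds(),
                         min_nuclei = 200L,
                         out_dir = NULL) {
  sim <- simulate_screen_tables(config)
  kept <- retain_wells(sim$wells, min_nuclei)
  wells <- plate_zscores(kept$retained)

  assay <- wells[wells$condition == "assay", ]
  z_by_rep <- split(assay, assay$replicate)
  genes <- sort(unique(assay$gene))
  z_table <- data.frame(
    gene = genes,
    z_rep1 = z_by_rep[[1]]$z[match(genes, z_by_rep[[1]]$gene)],
    z_rep2 = if (length(z_by_rep) >= 2)
      z_by_rep[[2]]$z[match(genes, z_by_rep[[2]]$gene)] else NA_real_)
  hits <- call_primary_hits(z_table, thresholds)

  truth_cls <- sim$truth$class[match(hits$gene, sim$truth$gene)]
  called <- c("suppressor" = "NIPBL-like", "enhancer" = "WAPL/PDS5-like",
              "none" = "none")[truth_cls]
  confusion <- table(truth = called, called = hits$class)

  manifest <- list(
    config = unclass(config), thresholds = unclass(thresholds),
    min_nuclei = as.integer(min_nuclei),
    n_wells_simulated = nrow(sim$wells),
    n_wells_retained = nrow(kept$retained))
  result <- list(wells = wells, dropped = kept$dropped, z_table = z_table,
                 hits = hits, truth = sim$truth, confusion = confusion,
                 manifest = manifest)

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    files <- c(wells = "wells.csv", z_table = "z_table.csv",
               hits = "hits.csv", truth = "truth.csv")
    for (nm in names(files)) {
      utils::write.csv(result[[nm]], file.path(out_dir, files[[nm]]),
                       row.names = FALSE)
    }
    paths <- file.path(out_dir, files)
    manifest$files <- lapply(seq_along(paths), function(i)
      list(name = unname(files[i]), md5 = unname(tools::md5sum(paths[i]))))
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    result$manifest <- manifest
  }
  result
}
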