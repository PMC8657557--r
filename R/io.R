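## Plain-text readers/writers for the pipeline's tabular formats:
## probe manifest CSV, probes x samples matrices as TSV (probe_id first
## column), sample sheet CSV, outline vertex CSV and 0/1 mask grids.
## The matrix reader also ingests GEO series-matrix-style beta tables
## (probe identifier column followed by one column per sample).

#' Write / read a probes-by-samples matrix as TSV
#'
#' The first column is \code{probe_id}; remaining columns are samples.
#'
#' @param m matrix with probe rownames and sample colnames.
#' @param path file path.
#' @return \code{readMatrixTSV} returns the matrix.
#' @export
writeMatrixTSV <- function(m, path) {
  df <- data.frame(probe_id = rownames(m), m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' @rdname writeMatrixTSV
#' @export
readMatrixTSV <- function(path) {
  df <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  m
}

#' Write / read a probe manifest CSV
#'
#' @param manifest manifest data.frame (see \code{\link{simulateManifest}}).
#' @param path file path.
#' @return \code{readManifest} returns the manifest data.frame.
#' @export
writeManifest <- function(manifest, path) {
  write.csv(manifest, path, row.names = FALSE, quote = FALSE)
}

#' @rdname writeManifest
#' @export
readManifest <- function(path) {
  man <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("probe_id", "design_type", "chrom", "pos", "gene",
            "is_cpg", "is_snp_associated", "is_multimapping")
  miss <- setdiff(need, colnames(man))
  if (length(miss))
    stop("manifest missing columns: ", paste(miss, collapse = ", "), call. = FALSE)
  man$gene[is.na(man$gene)] <- ""
  man
}

#' Write / read a sample sheet CSV
#'
#' Columns: \code{sample_id}, \code{group}, \code{replicate}.
#'
#' @param sampleInfo sample sheet data.frame.
#' @param path file path.
#' @return \code{readSampleSheet} returns the data.frame.
#' @export
writeSampleSheet <- function(sampleInfo, path) {
  write.csv(sampleInfo, path, row.names = FALSE, quote = FALSE)
}

#' @rdname writeSampleSheet
#' @export
readSampleSheet <- function(path) {
  ss <- read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("sample_id", "group", "replicate") %in% colnames(ss)))
    stop("sample sheet needs sample_id, group, replicate columns", call. = FALSE)
  ss
}

#' Assemble a MethylationExperiment from files
#'
#' Reads the beta, detection-p and bead-count TSV matrices, the manifest
#' CSV and the sample sheet CSV, aligns probes and samples, and returns a
#' validated experiment. Suitable for ingesting externally exported
#' (e.g. GEO series-matrix-style) beta tables alongside matching
#' detection-p / bead-count tables.
#'
#' @param betaPath,detPPath,beadPath matrix TSV paths.
#' @param manifestPath manifest CSV path.
#' @param samplesPath sample sheet CSV path.
#' @return a \linkS4class{MethylationExperiment}.
#' @export
readMethylationExperiment <- function(betaPath, detPPath, beadPath,
                                      manifestPath, samplesPath) {
  beta <- readMatrixTSV(betaPath)
  detp <- readMatrixTSV(detPPath)
  beads <- readMatrixTSV(beadPath)
  man <- readManifest(manifestPath)
  ss <- readSampleSheet(samplesPath)
  common <- intersect(rownames(beta), man$probe_id)
  if (length(common) < nrow(beta))
    stop("probes absent from manifest: ",
         paste(utils::head(setdiff(rownames(beta), common), 5), collapse = ", "),
         call. = FALSE)
  man <- man[match(rownames(beta), man$probe_id), ]
  ss <- ss[match(colnames(beta), ss$sample_id), ]
  if (any(is.na(ss$sample_id)))
    stop("samples absent from sample sheet", call. = FALSE)
  MethylationExperiment(beta, detp[rownames(beta), colnames(beta)],
                        beads[rownames(beta), colnames(beta)], man, ss)
}

#' Write / read cell outlines as a vertex-list CSV
#'
#' Long format with columns \code{cell_id}, \code{vertex_index},
#' \code{x}, \code{y}.
#'
#' @param outlines named list of vertex matrices.
#' @param path file path.
#' @return \code{readOutlines} returns a named list of vertex matrices.
#' @export
writeOutlines <- function(outlines, path) {
  rows <- lapply(names(outlines), function(id) {
    v <- outlines[[id]]
    data.frame(cell_id = id, vertex_index = seq_len(nrow(v)),
               x = v[, 1], y = v[, 2], stringsAsFactors = FALSE)
  })
  write.csv(do.call(rbind, rows), path, row.names = FALSE, quote = FALSE)
}

#' @rdname writeOutlines
#' @export
readOutlines <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  sp <- split(df[order(df$vertex_index), ], df$cell_id[order(df$vertex_index)])
  lapply(sp, function(d) cbind(x = d$x, y = d$y))
}

#' Write / read a binary mask as a plain-text 0/1 grid
#'
#' Space-separated rows of 0s and 1s.
#'
#' @param mask 0/1 integer matrix.
#' @param path file path.
#' @return \code{readMaskText} returns the integer matrix.
#' @export
writeMaskText <- function(mask, path) {
  write.table(mask, path, sep = " ", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
}

#' @rdname writeMaskText
#' @export
readMaskText <- function(path) {
  m <- as.matrix(read.table(path, header = FALSE))
  dimnames(m) <- NULL
  storage.mode(m) <- "integer"
  m
}
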