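#' Read and write the sample sheet
#'
#' The sample sheet maps each PCR sample to its station, depth layer,
#' replicate and negative-control status, and carries planar station
#' coordinates in metres (columns \code{sample_id, station_id, layer,
#' replicate, is_negative, x_m, y_m}).
#'
#' @param path CSV file path.
#' @return a data.frame with one row per PCR sample.
#' @export
readSampleSheet <- function(path) {
  ss <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("sample_id", "station_id", "layer", "replicate", "is_negative",
            "x_m", "y_m")
  miss <- setdiff(need, names(ss))
  if (length(miss))
    stop("sample sheet is missing columns: ", paste(miss, collapse = ", "))
  ss$is_negative <- as.logical(ss$is_negative)
  if (anyDuplicated(ss$sample_id)) stop("duplicate sample_id in sample sheet")
  ss
}

#' @rdname readSampleSheet
#' @param sheet sample-sheet data.frame.
#' @export
writeSampleSheet <- function(sheet, path) {
  write.csv(sheet, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read and write a structured reference database FASTA
#'
#' Headers follow the dialect
#' \code{>ACC|family|genus|species|habitat|local:\{0,1\}|fishery:\{0,1\}}.
#'
#' @param path FASTA file path.
#' @return data.frame with columns \code{accession, family, genus, species,
#'   habitat, local, fishery, sequence}.
#' @export
readReferenceFasta <- function(path) {
  x <- readDNAStringSet(path)
  parts <- strsplit(names(x), "|", fixed = TRUE)
  bad <- lengths(parts) != 7L
  if (any(bad))
    stop("malformed reference header(s): ", names(x)[bad][1])
  m <- do.call(rbind, parts)
  data.frame(accession = m[, 1], family = m[, 2], genus = m[, 3],
             species = m[, 4], habitat = m[, 5],
             local = sub("^local:", "", m[, 6]) == "1",
             fishery = sub("^fishery:", "", m[, 7]) == "1",
             sequence = as.character(x), stringsAsFactors = FALSE)
}

#' @rdname readReferenceFasta
#' @param ref reference data.frame as returned by [readReferenceFasta()] or
#'   [generateReferenceDb()].
#' @export
writeReferenceFasta <- function(ref, path) {
  hdr <- sprintf("%s|%s|%s|%s|%s|local:%d|fishery:%d", ref$accession,
                 ref$family, ref$genus, ref$species, ref$habitat,
                 as.integer(ref$local), as.integer(ref$fishery))
  x <- DNAStringSet(ref$sequence)
  names(x) <- hdr
  writeXStringSet(x, path)
  invisible(path)
}

#' Read a local-species checklist
#'
#' TSV with columns \code{species, genus, local} and an optional
#' \code{substitute_for} column naming the (non-local) assigned species that a
#' checklist species should replace during curation.
#'
#' @param path TSV file path.
#' @return data.frame checklist.
#' @export
readChecklist <- function(path) {
  cl <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("species", "genus", "local")
  miss <- setdiff(need, names(cl))
  if (length(miss))
    stop("checklist is missing columns: ", paste(miss, collapse = ", "))
  cl$local <- as.logical(cl$local)
  if (is.null(cl$substitute_for)) cl$substitute_for <- NA_character_
  cl$substitute_for[!nzchar(cl$substitute_for)] <- NA_character_
  cl
}

#' Read an underwater visual-census table
#'
#' TSV with columns \code{census_id, species, count}.
#'
#' @param path TSV file path.
#' @return data.frame census table.
#' @export
readCensusTable <- function(path) {
  cen <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("census_id", "species", "count")
  miss <- setdiff(need, names(cen))
  if (length(miss))
    stop("census table is missing columns: ", paste(miss, collapse = ", "))
  if (any(cen$count < 0)) stop("census counts must be >= 0")
  cen
}

#' Export a detection matrix as a long-format TSV
#'
#' One row per sample x taxon combination with columns
#' \code{station,layer,replicate,taxon,reads,detected}.
#'
#' @param dm a [DetectionMatrix-class].
#' @param path output TSV path.
#' @export
writeDetectionMatrix <- function(dm, path) {
  cd <- as.data.frame(colData(dm))
  rd <- as.data.frame(rowData(dm))
  cnt <- readCounts(dm)
  det <- detections(dm)
  long <- data.frame(
    station = rep(cd$station_id, each = nrow(dm)),
    layer = rep(cd$layer, each = nrow(dm)),
    replicate = rep(cd$replicate, each = nrow(dm)),
    taxon = rep(rd$taxon, ncol(dm)),
    reads = as.vector(cnt),
    detected = as.vector(det))
  write.table(long, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
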