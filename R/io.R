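#' Read a gene-level count matrix
#'
#' Reads a tab-separated count file in the featureCounts dialect: a header
#' row, a first column of gene IDs (named \code{gene_id} or \code{Geneid}),
#' an optional \code{length}/\code{Length} column of exonic gene lengths,
#' then one column of integer counts per sample.
#'
#' @param path path to the counts TSV.
#' @param sampleTable sample design: a data.frame (see [TissueCounts()]) or
#'   the path to a sample sheet CSV (see [readSampleSheet()]).
#' @param geneLengths optional named vector of gene lengths (bp), e.g. from
#'   [geneLengthsFromGff3()]; required when the file has no length column.
#' @return a [TissueCounts-class] object, ordering preserved from the file.
#' @export
readCounts <- function(path, sampleTable, geneLengths = NULL) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          check.names = FALSE, stringsAsFactors = FALSE)
  .assertThat(ncol(df) >= 2, "counts file needs gene IDs plus >= 1 sample")
  idcol <- colnames(df)[1]
  gene_ids <- as.character(df[[idcol]])
  dup <- unique(gene_ids[duplicated(gene_ids)])
  .assertThat(length(dup) == 0,
              paste0("duplicated gene ID(s) in counts file: ",
                     paste(utils::head(dup, 5), collapse = ", ")))
  df[[idcol]] <- NULL
  lenIdx <- which(tolower(colnames(df)) == "length")
  fileLengths <- NULL
  if (length(lenIdx)) {
    fileLengths <- stats::setNames(as.numeric(df[[lenIdx[1]]]), gene_ids)
    df[[lenIdx[1]]] <- NULL
  }
  for (j in seq_along(df)) {
    v <- df[[j]]
    if (!is.numeric(v)) {
      bad <- which(is.na(suppressWarnings(as.numeric(v))))[1]
      stop("non-numeric count at gene '", gene_ids[bad], "', sample '",
           colnames(df)[j], "'", call. = FALSE)
    }
    if (any(v < 0, na.rm = TRUE)) {
      bad <- which(v < 0)[1]
      stop("negative count at gene '", gene_ids[bad], "', sample '",
           colnames(df)[j], "'", call. = FALSE)
    }
    if (any(v != round(v), na.rm = TRUE)) {
      bad <- which(v != round(v))[1]
      stop("non-integer count at gene '", gene_ids[bad], "', sample '",
           colnames(df)[j], "'", call. = FALSE)
    }
  }
  counts <- as.matrix(df)
  rownames(counts) <- gene_ids
  lengths <- if (!is.null(fileLengths)) fileLengths else geneLengths
  .assertThat(!is.null(lengths),
              paste0("counts file has no length column and no geneLengths ",
                     "were supplied; provide lengths from a GFF3 annotation"))
  if (!is.null(names(lengths))) lengths <- .matchGeneIds(lengths, gene_ids)
  if (is.character(sampleTable) && length(sampleTable) == 1)
    sampleTable <- readSampleSheet(sampleTable)
  TissueCounts(counts, lengths, sampleTable)
}

## ITAG-style IDs carry version suffixes inconsistently across files
## (Solyc05g054360.4 vs Solyc05g054360); strip them only when the exact
## match fails.
#' @noRd
.matchGeneIds <- function(named, wanted) {
  out <- named[wanted]
  missIdx <- which(is.na(names(out)) | !(wanted %in% names(named)))
  if (length(missIdx)) {
    stripped <- sub("\\.[0-9]+$", "", names(named))
    for (i in missIdx) {
      hit <- which(stripped == sub("\\.[0-9]+$", "", wanted[i]))
      .assertThat(length(hit) >= 1,
                  paste0("no length for gene(s): ", wanted[i]))
      out[i] <- named[hit[1]]
    }
  }
  names(out) <- wanted
  out
}

#' Write a TissueCounts count matrix
#'
#' Writes the TSV dialect accepted by [readCounts()]: \code{gene_id},
#' \code{length}, then one column per sample.
#'
#' @param x a [TissueCounts-class] object.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
writeCounts <- function(x, path) {
  df <- data.frame(gene_id = rownames(x),
                   length = unname(geneLengths(x)),
                   SummarizedExperiment::assay(x, "counts"),
                   check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Gene lengths from a GFF3 annotation
#'
#' Computes, per gene, the number of bases covered by the union of its
#' exons (overlapping exons merged; GFF3 coordinates are 1-based inclusive,
#' so a single-base exon has length 1). Exon \code{Parent} attributes are
#' resolved through mRNA/transcript features up to the owning gene. Strand
#' is ignored: length is strand-invariant.
#'
#' @param path path to a GFF3 file with gene and exon features.
#' @return named integer vector of lengths (bp) per gene ID. Genes without
#'   exons fall back to the gene span (with a warning); exons whose Parent
#'   cannot be resolved are skipped with a warning.
#' @export
geneLengthsFromGff3 <- function(path) {
  gr <- rtracklayer::import(path, format = "gff3")
  mc <- S4Vectors::mcols(gr)
  type <- as.character(mc$type)
  ids <- as.character(mc$ID)
  parentList <- mc$Parent  # CharacterList; may be empty per feature
  idType <- stats::setNames(type, ids)
  idParent <- stats::setNames(
    vapply(parentList, function(p) if (length(p)) p[[1]] else NA_character_,
           character(1)),
    ids)

  resolveGene <- function(parent) {
    seen <- character()
    cur <- parent
    while (!is.na(cur) && cur %in% names(idType) && !(cur %in% seen)) {
      if (idType[[cur]] == "gene") return(cur)
      seen <- c(seen, cur)
      cur <- idParent[[cur]]
    }
    NA_character_
  }

  isExon <- type == "exon"
  exonParents <- parentList[isExon]
  exonRanges <- gr[isExon]
  # an exon may be shared by several transcripts; assign to each parent's gene
  expandIdx <- rep(seq_along(exonRanges), lengths(exonParents))
  flatParents <- unlist(exonParents, use.names = FALSE)
  exonGene <- vapply(unique(flatParents), resolveGene, character(1))
  geneOfExon <- exonGene[flatParents]
  unresolved <- is.na(geneOfExon)
  if (any(unresolved)) {
    warning(sum(unresolved), " exon(s) with unresolvable Parent skipped",
            call. = FALSE)
    expandIdx <- expandIdx[!unresolved]
    geneOfExon <- geneOfExon[!unresolved]
  }
  exonByGene <- split(GenomicRanges::ranges(exonRanges)[expandIdx], geneOfExon)
  lengths <- vapply(exonByGene,
                    function(r) sum(IRanges::width(IRanges::reduce(r))),
                    numeric(1))

  geneIds <- ids[type == "gene"]
  out <- stats::setNames(integer(length(geneIds)), geneIds)
  out[names(lengths)] <- as.integer(lengths)
  noExon <- setdiff(geneIds, names(lengths))
  if (length(noExon)) {
    warning("gene(s) without exons fall back to gene span: ",
            paste(utils::head(noExon, 5), collapse = ", "), call. = FALSE)
    spans <- GenomicRanges::width(gr[type == "gene"])
    names(spans) <- geneIds
    out[noExon] <- as.integer(spans[noExon])
  }
  out
}

#' Read a sample sheet
#'
#' CSV with columns \code{sample_id,species,tissue,subtissue,bio_rep}.
#' Species must be \code{SL}/\code{SP}; tissue must be \code{leaf},
#' \code{pollen} or \code{style}; \code{subtissue} may be empty.
#'
#' @param path path to the CSV.
#' @return a validated data.frame.
#' @export
readSampleSheet <- function(path) {
  st <- utils::read.csv(path, stringsAsFactors = FALSE)
  st <- .normalizeSampleTable(st)
  badSp <- setdiff(unique(st$species), .speciesLevels())
  .assertThat(length(badSp) == 0,
              paste0("unknown species label(s): ", paste(badSp, collapse = ", "),
                     "; allowed: ", paste(.speciesLevels(), collapse = ", ")))
  badTi <- setdiff(unique(st$tissue), .tissueLevels())
  .assertThat(length(badTi) == 0,
              paste0("unknown tissue label(s): ", paste(badTi, collapse = ", "),
                     "; allowed: ", paste(.tissueLevels(), collapse = ", ")))
  .assertThat(all(st$bio_rep >= 1), "bio_rep must be a positive integer")
  key <- paste(st$species, st$tissue, st$subtissue, st$bio_rep)
  .assertThat(!anyDuplicated(key),
              paste0("duplicated design row: ", key[duplicated(key)][1]))
  st
}

#' Read a functional-annotation table
#'
#' Two-column TSV: \code{gene_id<TAB>description}.
#'
#' @param path path to the TSV.
#' @return data.frame with unique \code{gene_id} and \code{description}.
#' @export
readAnnotation <- function(path) {
  ann <- utils::read.delim(path, header = TRUE, sep = "\t",
                           quote = "", stringsAsFactors = FALSE)
  .assertThat(all(c("gene_id", "description") %in% colnames(ann)),
              "annotation TSV needs columns gene_id and description")
  dup <- unique(ann$gene_id[duplicated(ann$gene_id)])
  .assertThat(length(dup) == 0,
              paste0("duplicated gene ID(s) in annotation: ",
                     paste(utils::head(dup, 5), collapse = ", ")))
  ann[, c("gene_id", "description")]
}

#' Read a pollen-tube phenotype table
#'
#' CSV with columns \code{assay_type} (\code{in_vitro}/\code{in_vivo}),
#' \code{species}, \code{donor_id}, \code{recipient_id} (empty for in
#' vitro), \code{tech_rep}, \code{elapsed_h}, \code{style_length_um} (in
#' vivo), \code{n_viable}, \code{n_germinated}, \code{pollen_diameters_um}
#' and \code{tube_lengths_um}. The two list-valued fields are
#' semicolon-delimited within a cell.
#'
#' @param path path to the CSV.
#' @return data.frame with list columns \code{pollen_diameters_um} and
#'   \code{tube_lengths_um}, validated against the assay invariants.
#' @export
readPhenotypes <- function(path) {
  pt <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = c(pollen_diameters_um = "character",
                                       tube_lengths_um = "character"))
  validatePhenotypes(.parsePhenotypeLists(pt))
}

#' @noRd
.parsePhenotypeLists <- function(pt) {
  splitNum <- function(v) {
    lapply(v, function(s) {
      if (is.na(s) || !nzchar(s)) numeric(0)
      else as.numeric(strsplit(s, ";", fixed = TRUE)[[1]])
    })
  }
  pt$pollen_diameters_um <- splitNum(pt$pollen_diameters_um)
  pt$tube_lengths_um <- splitNum(pt$tube_lengths_um)
  pt
}

#' Validate a phenotype table
#'
#' @param pt data.frame in the layout of [readPhenotypes()] (list columns
#'   already parsed).
#' @return \code{pt}, invisibly validated; errors name the offending record.
#' @export
validatePhenotypes <- function(pt) {
  need <- c("assay_type", "species", "donor_id", "recipient_id", "tech_rep",
            "elapsed_h", "style_length_um", "n_viable", "n_germinated",
            "pollen_diameters_um", "tube_lengths_um")
  miss <- setdiff(need, colnames(pt))
  .assertThat(length(miss) == 0,
              paste0("phenotype table is missing column(s): ",
                     paste(miss, collapse = ", ")))
  badAssay <- setdiff(unique(pt$assay_type), c("in_vitro", "in_vivo"))
  .assertThat(length(badAssay) == 0,
              paste0("unknown assay_type: ", paste(badAssay, collapse = ", "),
                     "; allowed: in_vitro, in_vivo"))
  badSp <- setdiff(unique(pt$species), .speciesLevels())
  .assertThat(length(badSp) == 0,
              paste0("unknown species label(s): ", paste(badSp, collapse = ", ")))
  rec <- function(i) paste0("record ", i, " (", pt$species[i], " donor ",
                            pt$donor_id[i], ")")
  for (i in seq_len(nrow(pt))) {
    .assertThat(!is.na(pt$elapsed_h[i]) && pt$elapsed_h[i] > 0,
                paste0("elapsed_h must be > 0 at ", rec(i)))
    tl <- pt$tube_lengths_um[[i]]
    .assertThat(all(tl > 0), paste0("tube lengths must be > 0 at ", rec(i)))
    pd <- pt$pollen_diameters_um[[i]]
    .assertThat(all(pd > 0), paste0("pollen diameters must be > 0 at ", rec(i)))
    if (pt$assay_type[i] == "in_vitro") {
      if (!is.na(pt$n_viable[i]) && !is.na(pt$n_germinated[i]))
        .assertThat(pt$n_germinated[i] <= pt$n_viable[i],
                    paste0("n_germinated > n_viable at ", rec(i)))
    } else {
      .assertThat(!is.na(pt$style_length_um[i]) && pt$style_length_um[i] > 0,
                  paste0("in vivo record needs style_length_um > 0 at ", rec(i)))
    }
  }
  pt
}

#' Write a phenotype table
#'
#' @param pt phenotype data.frame with list columns.
#' @param path output CSV path.
#' @return \code{path}, invisibly.
#' @export
writePhenotypes <- function(pt, path) {
  out <- pt
  join <- function(col) vapply(col, function(v)
    paste(format(v, trim = TRUE, scientific = FALSE), collapse = ";"),
    character(1))
  out$pollen_diameters_um <- join(pt$pollen_diameters_um)
  out$tube_lengths_um <- join(pt$tube_lengths_um)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write a result table deterministically
#'
#' Emits TSV (or JSON for \code{.json} paths) with a fixed column order,
#' rows sorted by the first identifier column, and doubles serialized at 6
#' significant digits, so repeated runs are byte-identical.
#'
#' @param x data.frame of results.
#' @param path output path; extension selects TSV or JSON.
#' @return \code{path}, invisibly.
#' @export
writeResultTable <- function(x, path) {
  x <- as.data.frame(x)
  if (nrow(x) > 1 && ncol(x) >= 1)
    x <- x[order(x[[1]], method = "radix"), , drop = FALSE]
  x <- .signifCols(x)
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(x, path, dataframe = "rows", auto_unbox = TRUE,
                         digits = NA, pretty = TRUE)
  } else {
    utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}
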