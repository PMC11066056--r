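#' RPKM abundance of a reference genome or gene
#'
#' Reads per kilobase of reference per million library reads:
#' `mapped_reads * 1e6 / (total_reads * length_kb)`. Used for SAR11
#' metagenome-assembled genomes (MAGs) and 16S rRNA gene sequences;
#' `total_reads` is the library size of the sample.
#'
#' @param mapped_reads reads mapped to the reference (>= 0; multi-mapping
#'   may exceed the library size).
#' @param total_reads library size of the sample (> 0).
#' @param length_kb reference length in kilobase pairs (> 0).
#' @return RPKM value(s); vectorized.
#' @export
mag_rpkm <- function(mapped_reads, total_reads, length_kb) {
  if (any(total_reads <= 0)) stop("total_reads must be > 0")
  if (any(length_kb <= 0)) stop("length_kb must be > 0")
  if (any(mapped_reads < 0)) stop("mapped_reads must be >= 0")
  mapped_reads * 1e6 / (total_reads * length_kb)
}

#' Phage abundance relative to the SAR11 community
#'
#' Because the assessed pelagiphages are SAR11-specific, their abundance is
#' normalized to the SAR11 community rather than to the whole library:
#' `phage_mapped * 1e6 / (sum_sar11_mag_mapped * phage_length_kb)`.
#'
#' @param phage_mapped reads mapped to the phage genome (>= 0).
#' @param sum_sar11_mag_mapped per-sample sum of reads mapped to all SAR11
#'   MAGs; a zero denominator yields `NA` (flagged undefined, not 0).
#' @param phage_length_kb phage genome length in kilobase pairs (> 0).
#' @return relative abundance value(s); vectorized; `NA` where the SAR11
#'   denominator is zero.
#' @export
phage_relative_rpkm <- function(phage_mapped, sum_sar11_mag_mapped,
                                phage_length_kb) {
  if (any(phage_length_kb <= 0)) stop("phage_length_kb must be > 0")
  if (any(phage_mapped < 0)) stop("phage_mapped must be >= 0")
  out <- phage_mapped * 1e6 / (sum_sar11_mag_mapped * phage_length_kb)
  out[sum_sar11_mag_mapped <= 0] <- NA_real_
  out
}

#' Compute an abundance table from mapping counts
#'
#' Applies [mag_rpkm()] to `sar11_mag` and `rrna_gene` references and
#' [phage_relative_rpkm()] to `phage` references, the latter against the
#' per-sample sum of SAR11 MAG mapped reads. Samples containing a phage but
#' no SAR11 MAG reads get flagged-undefined (`NA`) phage records.
#'
#' @param counts data.frame with columns `sample`, `reference`,
#'   `reference_class` (one of `sar11_mag`, `rrna_gene`, `phage`),
#'   `mapped_reads`, `length_kb`, `total_reads`.
#' @return data.frame of records: `sample`, `reference`, `rpkm`,
#'   `formula` (`mag_rpkm` or `phage_relative`), `undefined`.
#' @export
compute_abundance_table <- function(counts) {
  need <- c("sample", "reference", "reference_class", "mapped_reads",
            "length_kb", "total_reads")
  if (!all(need %in% names(counts)))
    stop("counts must have columns: ", paste(need, collapse = ", "))
  if (!nrow(counts))
    return(data.frame(sample = character(0), reference = character(0),
                      rpkm = numeric(0), formula = character(0),
                      undefined = logical(0)))
  bad <- setdiff(unique(counts$reference_class),
                 c("sar11_mag", "rrna_gene", "phage"))
  if (length(bad)) stop("unknown reference_class: ",
                        paste(bad, collapse = ", "))
  mag_rows <- counts$reference_class %in% c("sar11_mag", "rrna_gene")
  sar_sum <- tapply(counts$mapped_reads[counts$reference_class ==
                                          "sar11_mag"],
                    counts$sample[counts$reference_class == "sar11_mag"],
                    sum)
  out <- counts[, c("sample", "reference")]
  out$rpkm <- NA_real_
  out$formula <- ifelse(mag_rows, "mag_rpkm", "phage_relative")
  out$rpkm[mag_rows] <- mag_rpkm(counts$mapped_reads[mag_rows],
                                 counts$total_reads[mag_rows],
                                 counts$length_kb[mag_rows])
  ph <- which(!mag_rows)
  if (length(ph)) {
    denom <- as.numeric(sar_sum[as.character(counts$sample[ph])])
    denom[is.na(denom)] <- 0
    out$rpkm[ph] <- phage_relative_rpkm(counts$mapped_reads[ph], denom,
                                        counts$length_kb[ph])
  }
  out$undefined <- is.na(out$rpkm)
  rownames(out) <- NULL
  out
}

#' Toy exact-substring read mapper
#'
#' Counts, per reference, the reads that occur verbatim (either strand) as
#' a substring of the reference. This is not an aligner: it exists so that
#' fully synthetic end-to-end abundance tests can run without external
#' mapping tools.
#'
#' @param reads character vector of read sequences.
#' @param references named character vector of reference sequences.
#' @return named integer vector of mapped-read counts per reference.
#' @export
toy_map_reads <- function(reads, references) {
  if (is.null(names(references)))
    names(references) <- paste0("ref", seq_along(references))
  vapply(references, function(ref) {
    ref <- toupper(ref)
    sum(vapply(toupper(reads), function(rd) {
      grepl(rd, ref, fixed = TRUE) || grepl(revcomp(rd), ref, fixed = TRUE)
    }, logical(1)))
  }, integer(1))
}

#' Read / write mapping-count and abundance TSV files
#'
#' @param path TSV path.
#' @return `read_mapping_counts` returns the counts data.frame.
#' @export
read_mapping_counts <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE)
}

#' @rdname read_mapping_counts
#' @param table a data.frame (counts or abundance records).
#' @export
write_abundance_tsv <- function(table, path) {
  utils::write.table(table, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
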