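# Genome annotation container and readers.
#
# Coordinate convention: every interval in memory is 0-based half-open
# [start, end).  BED is native; GTF and RepeatMasker .out are 1-based
# inclusive and converted on read.  The TSS of a '-' strand gene is the
# LAST base of the annotated interval (a base, not a boundary).

.te_loci_cols <- c("locus_id", "chrom", "start", "end", "strand",
                   "subfamily", "family")
.gene_cols <- c("gene_id", "chrom", "tss", "strand", "class")

.check_intervals <- function(df, chrom_sizes = NULL, what = "interval") {
  stopifnot(is.data.frame(df))
  if (nrow(df) == 0L) return(invisible(df))
  bad <- which(!(df$start >= 0 & df$start < df$end))
  if (length(bad))
    stop(sprintf("invalid %s coordinates (need 0 <= start < end) at row %d",
                 what, bad[1]), call. = FALSE)
  if (!all(df$strand %in% c("+", "-")))
    stop(sprintf("%s strand must be '+' or '-'", what), call. = FALSE)
  if (!is.null(chrom_sizes)) {
    unknown <- setdiff(unique(df$chrom), names(chrom_sizes))
    if (length(unknown))
      stop(sprintf("unknown chromosome(s) in %s table: %s", what,
                   paste(unknown, collapse = ", ")), call. = FALSE)
    over <- which(df$end > chrom_sizes[df$chrom])
    if (length(over))
      stop(sprintf("%s at row %d extends past the end of %s",
                   what, over[1], df$chrom[over[1]]), call. = FALSE)
  }
  invisible(df)
}

#' Assemble a genome annotation
#'
#' Bundles chromosome sizes, a TE locus table and a gene/TSS table into the
#' coordinate universe used by all interval operations.  All coordinates
#' are 0-based half-open.
#'
#' @param chrom_sizes named numeric vector, chromosome -> length (bp).
#' @param te_loci data.frame with columns `locus_id, chrom, start, end,
#'   strand, subfamily, family`.  May have zero rows.
#' @param genes data.frame with columns `gene_id, chrom, tss, strand,
#'   class` where `class` is `"gene"` or `"kznf"`.
#' @return An object of class `genome_annotation`.
#' @export
genome_annotation <- function(chrom_sizes,
                              te_loci = empty_te_loci(),
                              genes = empty_genes()) {
  if (is.null(names(chrom_sizes)) || any(!nzchar(names(chrom_sizes))))
    stop("chrom_sizes must be a named vector", call. = FALSE)
  if (any(chrom_sizes <= 0)) stop("chromosome lengths must be positive",
                                  call. = FALSE)
  te_loci <- as.data.frame(te_loci)
  genes <- as.data.frame(genes)
  if (!all(.te_loci_cols %in% names(te_loci)))
    stop("te_loci must have columns: ", paste(.te_loci_cols, collapse = ", "),
         call. = FALSE)
  if (!all(.gene_cols %in% names(genes)))
    stop("genes must have columns: ", paste(.gene_cols, collapse = ", "),
         call. = FALSE)
  .check_intervals(te_loci, chrom_sizes, "TE locus")
  if (anyDuplicated(te_loci$locus_id))
    stop("duplicate locus_id in te_loci", call. = FALSE)
  if (anyDuplicated(genes$gene_id))
    stop("duplicate gene_id in genes", call. = FALSE)
  if (nrow(te_loci)) {
    fam_per_sub <- tapply(te_loci$family, te_loci$subfamily,
                          function(x) length(unique(x)))
    if (any(fam_per_sub > 1))
      stop("subfamily mapped to more than one family: ",
           names(fam_per_sub)[fam_per_sub > 1][1], call. = FALSE)
  }
  if (nrow(genes)) {
    if (!all(genes$class %in% c("gene", "kznf")))
      stop("gene class must be 'gene' or 'kznf'", call. = FALSE)
    unknown <- setdiff(unique(genes$chrom), names(chrom_sizes))
    if (length(unknown))
      stop("unknown chromosome(s) in genes table: ",
           paste(unknown, collapse = ", "), call. = FALSE)
    bad <- which(genes$tss < 0 | genes$tss >= chrom_sizes[genes$chrom])
    if (length(bad))
      stop(sprintf("TSS outside chromosome at gene row %d", bad[1]),
           call. = FALSE)
  }
  structure(list(chrom_sizes = chrom_sizes,
                 te_loci = te_loci[, .te_loci_cols],
                 genes = genes[, .gene_cols]),
            class = "genome_annotation")
}

#' @export
print.genome_annotation <- function(x, ...) {
  cat(sprintf("genome_annotation: %d chromosome(s), %.0f bp total\n",
              length(x$chrom_sizes), sum(x$chrom_sizes)))
  cat(sprintf("  %d TE loci in %d subfamilies / %d families\n",
              nrow(x$te_loci), length(unique(x$te_loci$subfamily)),
              length(unique(x$te_loci$family))))
  cat(sprintf("  %d genes (%d KZNF)\n", nrow(x$genes),
              sum(x$genes$class == "kznf")))
  invisible(x)
}

#' @rdname genome_annotation
#' @export
empty_te_loci <- function() {
  data.frame(locus_id = character(), chrom = character(),
             start = numeric(), end = numeric(), strand = character(),
             subfamily = character(), family = character())
}

#' @rdname genome_annotation
#' @export
empty_genes <- function() {
  data.frame(gene_id = character(), chrom = character(), tss = numeric(),
             strand = character(), class = character())
}

#' Read a TE locus annotation
#'
#' Parses TE loci from BED6 (0-based half-open, used as-is; an optional 7th
#' column gives the family) or from RepeatMasker `.out` (1-based inclusive;
#' start is converted by subtracting 1; the repeat name column gives the
#' subfamily and the class/family column the family).  When no family
#' information is available the family defaults to the subfamily.
#'
#' @param path file path.
#' @param format `"bed"` or `"repeatmasker_out"`.
#' @param chrom_sizes optional named vector; when supplied, loci on unknown
#'   chromosomes raise an error.
#' @param family_map optional named character vector mapping subfamily ->
#'   family, used for BED input without a family column.
#' @return A te_loci data.frame (see [genome_annotation()]).
#' @export
read_te_annotation <- function(path, format = c("bed", "repeatmasker_out"),
                               chrom_sizes = NULL, family_map = NULL) {
  format <- match.arg(format)
  lines <- readLines(path)
  if (format == "repeatmasker_out") {
    if (length(lines) < 3L)
      stop("RepeatMasker .out file must have 3 header lines", call. = FALSE)
    body <- lines[-(1:3)]
    offset <- 3L
  } else {
    body <- lines
    offset <- 0L
  }
  body_idx <- which(nzchar(trimws(body)))
  if (!length(body_idx)) {
    out <- empty_te_loci()
    .check_intervals(out, chrom_sizes, "TE locus")
    return(out)
  }
  rows <- lapply(body_idx, function(i) {
    f <- strsplit(trimws(body[i]), "\\s+")[[1]]
    lineno <- i + offset
    if (format == "bed") {
      if (length(f) < 6L)
        stop(sprintf("malformed BED line %d: expected >= 6 fields, got %d",
                     lineno, length(f)), call. = FALSE)
      start <- suppressWarnings(as.numeric(f[2]))
      end <- suppressWarnings(as.numeric(f[3]))
      if (is.na(start) || is.na(end))
        stop(sprintf("malformed BED line %d: non-numeric coordinates",
                     lineno), call. = FALSE)
      subfam <- f[4]
      fam <- if (length(f) >= 7L) f[7] else NA_character_
      data.frame(chrom = f[1], start = start, end = end, strand = f[6],
                 subfamily = subfam, family = fam)
    } else {
      if (length(f) < 11L)
        stop(sprintf("malformed RepeatMasker line %d: expected >= 11 fields",
                     lineno), call. = FALSE)
      begin <- suppressWarnings(as.numeric(f[6]))
      end <- suppressWarnings(as.numeric(f[7]))
      if (is.na(begin) || is.na(end))
        stop(sprintf("malformed RepeatMasker line %d: non-numeric coordinates",
                     lineno), call. = FALSE)
      strand <- if (f[9] == "C") "-" else f[9]
      data.frame(chrom = f[5], start = begin - 1, end = end, strand = strand,
                 subfamily = f[10], family = f[11])
    }
  })
  out <- do.call(rbind, rows)
  if (anyNA(out$family)) {
    if (!is.null(family_map)) {
      hit <- out$subfamily %in% names(family_map)
      out$family[is.na(out$family) & hit] <-
        family_map[out$subfamily[is.na(out$family) & hit]]
    }
    out$family[is.na(out$family)] <- out$subfamily[is.na(out$family)]
  }
  idx <- stats::ave(seq_len(nrow(out)), out$subfamily, FUN = seq_along)
  out$locus_id <- sprintf("%s.%d", out$subfamily, idx)
  out <- out[, .te_loci_cols]
  .check_intervals(out, chrom_sizes, "TE locus")
  out
}

#' Write TE loci as BED
#'
#' BED6 plus a 7th family column, so [read_te_annotation()] round-trips
#' coordinates, strand, subfamily and family exactly.
#'
#' @param te_loci a te_loci data.frame.
#' @param path output file.
#' @export
write_te_bed <- function(te_loci, path) {
  lines <- sprintf("%s\t%d\t%d\t%s\t0\t%s\t%s", te_loci$chrom,
                   as.integer(te_loci$start), as.integer(te_loci$end),
                   te_loci$subfamily, te_loci$strand, te_loci$family)
  writeLines(lines, path)
  invisible(path)
}

#' Read gene TSS annotation from GTF
#'
#' Imports `feature_type` records (default `"gene"`) from a GTF (1-based
#' inclusive) and reduces each gene to its transcription start site in
#' 0-based coordinates: `start - 1` on the '+' strand, `end - 1` (the last
#' base) on the '-' strand.  Genes whose IDs appear in `kznf_ids` are
#' classed `"kznf"`; the KZNF catalogue is supplied by the user, not
#' inferred.
#'
#' @param path GTF file path.
#' @param kznf_ids optional character vector of KRAB zinc-finger gene IDs.
#' @param feature_type GTF feature type to keep.
#' @return A genes data.frame (see [genome_annotation()]).
#' @export
read_gene_annotation <- function(path, kznf_ids = NULL,
                                 feature_type = "gene") {
  gr <- rtracklayer::import(path, format = "gtf")
  gr <- gr[as.character(gr$type) == feature_type]
  if (!length(gr)) return(empty_genes())
  if (is.null(gr$gene_id) || anyNA(gr$gene_id))
    stop("GTF records lack gene_id attributes", call. = FALSE)
  strand <- as.character(BiocGenerics::strand(gr))
  if (any(strand == "*"))
    stop("gene without strand: ", gr$gene_id[strand == "*"][1], call. = FALSE)
  if (anyDuplicated(gr$gene_id))
    stop("duplicate gene_id: ",
         gr$gene_id[duplicated(gr$gene_id)][1], call. = FALSE)
  tss <- ifelse(strand == "+", BiocGenerics::start(gr) - 1,
                BiocGenerics::end(gr) - 1)
  cls <- ifelse(gr$gene_id %in% kznf_ids, "kznf", "gene")
  data.frame(gene_id = gr$gene_id,
             chrom = as.character(GenomeInfoDb::seqnames(gr)),
             tss = as.numeric(tss), strand = strand, class = cls)
}
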