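#' Construct a transcript model
#'
#' @param transcript_id character label.
#' @param chrom chromosome name.
#' @param strand `"+"` or `"-"`.
#' @param exons data.frame with `start`, `end` (0-based half-open),
#'   non-overlapping; stored sorted by genomic coordinate.
#' @param cds_end optional CDS end coordinate.
#' @param polya_site optional polyadenylation site; when supplied it must
#'   equal the transcript's strand-aware 3' boundary (max end on `+`,
#'   min start on `-`). When `NA` it is filled in from the exons.
#' @return object of class `transcript_model`.
#' @export
transcript_model <- function(transcript_id, chrom, strand, exons,
                             cds_end = NA, polya_site = NA) {
  stopifnot(strand %in% c("+", "-"))
  if (!is.data.frame(exons) || !nrow(exons))
    stop("transcript lacking exons: ", transcript_id)
  exons <- exons[order(exons$start), c("start", "end"), drop = FALSE]
  rownames(exons) <- NULL
  if (nrow(exons) > 1 &&
      any(exons$start[-1] < exons$end[-nrow(exons)]))
    stop("overlapping exons in transcript ", transcript_id)
  end3 <- if (strand == "+") max(exons$end) else min(exons$start)
  if (is.na(polya_site)) polya_site <- end3
  else if (polya_site != end3)
    stop("polya_site of ", transcript_id,
         " does not equal its 3' boundary (", end3, ")")
  structure(list(transcript_id = transcript_id, chrom = chrom,
                 strand = strand, exons = exons, cds_end = cds_end,
                 polya_site = polya_site),
            class = "transcript_model")
}

#' Construct a gene model
#'
#' The strand-aware 3' terminus `end3` (max coordinate on `+`, min on
#' `-`) and the TSS are derived from the union of exon coordinates, or
#' checked against a declared span when one is given.
#'
#' @param gene_id character label.
#' @param chrom chromosome name.
#' @param strand `"+"` or `"-"`.
#' @param transcripts list of [transcript_model()] objects.
#' @param span optional declared gene span `c(start, end)`; every exon
#'   must lie within it.
#' @return object of class `gene_model` with fields `tss` and `end3`.
#' @export
gene_model <- function(gene_id, chrom, strand, transcripts, span = NULL) {
  stopifnot(strand %in% c("+", "-"), length(transcripts) >= 1)
  allex <- do.call(rbind, lapply(transcripts, `[[`, "exons"))
  lo <- min(allex$start); hi <- max(allex$end)
  if (!is.null(span) && (lo < span[1] || hi > span[2]))
    stop("exon outside declared span of gene ", gene_id)
  structure(list(gene_id = gene_id, chrom = chrom, strand = strand,
                 start = lo, end = hi,
                 tss = if (strand == "+") lo else hi,
                 end3 = if (strand == "+") hi else lo,
                 transcripts = transcripts),
            class = "gene_model")
}

#' @export
print.gene_model <- function(x, ...) {
  cat(sprintf("gene_model %s  %s:%d-%d (%s)  %d transcript(s)  end3=%d\n",
              x$gene_id, x$chrom, x$start, x$end, x$strand,
              length(x$transcripts), x$end3))
  invisible(x)
}

#' Read gene models from a GTF file
#'
#' GTF is 1-based inclusive; coordinates are converted to the package's
#' 0-based half-open convention on read. Transcripts are assembled from
#' `exon` features grouped by `transcript_id`; a transcript without exons
#' is an error. When a `gene` feature declares a span, exons must fall
#' inside it.
#'
#' @param path GTF file (optionally gzipped).
#' @return named list of [gene_model()] objects.
#' @export
read_genes <- function(path) {
  gr <- rtracklayer::import(path, format = "gtf")
  md <- S4Vectors::mcols(gr)
  type <- as.character(md$type)
  g_id <- as.character(md$gene_id)
  t_id <- if ("transcript_id" %in% names(md))
    as.character(md$transcript_id) else rep(NA_character_, length(gr))

  spans <- list()
  for (i in which(type == "gene"))
    spans[[g_id[i]]] <- c(GenomicRanges::start(gr)[i] - 1L,
                          GenomicRanges::end(gr)[i])

  ex <- which(type == "exon")
  if (!length(ex)) stop("GTF contains no exon features: ", path)
  # transcripts declared but exonless
  declared <- unique(stats::na.omit(t_id[type == "transcript"]))
  orphan <- setdiff(declared, unique(t_id[ex]))
  if (length(orphan))
    stop("transcript lacking exons: ", paste(orphan, collapse = ", "))

  exd <- data.frame(
    gene = g_id[ex], tx = t_id[ex],
    chrom = as.character(GenomicRanges::seqnames(gr))[ex],
    strand = as.character(GenomicRanges::strand(gr))[ex],
    start = GenomicRanges::start(gr)[ex] - 1L,  # to 0-based half-open
    end = GenomicRanges::end(gr)[ex],
    stringsAsFactors = FALSE)

  genes <- list()
  for (g in unique(exd$gene)) {
    sub <- exd[exd$gene == g, , drop = FALSE]
    txs <- lapply(split(sub, sub$tx), function(s) {
      transcript_model(s$tx[1], s$chrom[1], s$strand[1],
                       s[, c("start", "end")])
    })
    genes[[g]] <- gene_model(g, sub$chrom[1], sub$strand[1],
                             unname(txs), span = spans[[g]])
  }
  genes
}
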