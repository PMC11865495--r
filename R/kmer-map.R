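## Exact re-mapping of enriched k-mers onto a genome (both strands, up to
## max_hits sites per k-mer) and attribution of mapping sites to satellite
## annotation classes.

#' Map k-mers to a genome by exact match
#'
#' Reports every exact occurrence of each k-mer on either strand. A hit on
#' the minus strand means the reverse complement of the k-mer occurs at the
#' reported forward-strand coordinates. For reverse-complement-palindromic
#' k-mers the coincident +/- hits collapse to a single + hit. Hits are
#' enumerated left-to-right along each chromosome with + before - at equal
#' coordinates, and truncated at `max_hits` per k-mer; hits of saturated
#' k-mers carry `truncated = TRUE` so they remain identifiable.
#'
#' @param kmers character vector of k-mers (optionally named with ids; ids
#'   default to "1", "2", ...), a DNAStringSet, or a path to a FASTA file.
#' @param genome a `toy_genome`, DNAStringSet, named character vector, or
#'   FASTA path.
#' @param max_hits per-k-mer hit cap (the pipeline default mirrors a
#'   `-k 5000` exact-mapping setting).
#' @return GRanges of hits with metadata columns `kmer_id`, `kmer` and
#'   `truncated`; strand set per hit.
#' @export
map_exact <- function(kmers, genome, max_hits = 5000L) {
  if (is(kmers, "DNAStringSet")) kmers <- setNames(as.character(kmers),
                                                   names(kmers))
  if (is.character(kmers) && length(kmers) == 1L && file.exists(kmers) &&
      grepl("\\.(fa|fasta|fna)(\\.gz)?$", kmers)) {
    ss <- Biostrings::readDNAStringSet(kmers)
    kmers <- setNames(as.character(ss), names(ss))
  }
  if (is.character(genome) && length(genome) == 1L && file.exists(genome) &&
      grepl("\\.(fa|fasta|fna)(\\.gz)?$", genome)) {
    genome <- Biostrings::readDNAStringSet(genome)
  }
  seqs <- genome_seqs(genome)
  if (is.null(names(kmers))) names(kmers) <- as.character(seq_along(kmers))
  kmers <- toupper(kmers)
  bad <- grepl("[^ACGT]", kmers)
  if (any(bad)) {
    warning(sum(bad), " k-mer(s) with non-ACGT characters skipped")
    kmers <- kmers[!bad]
  }
  empty <- GenomicRanges::GRanges(
    seqnames = character(0), ranges = IRanges::IRanges(),
    strand = character(0), kmer_id = character(0), kmer = character(0),
    truncated = logical(0))
  if (!length(kmers)) return(empty)
  recs <- list()
  for (w in unique(nchar(kmers))) {
    sub <- kmers[nchar(kmers) == w]
    rc <- revcomp(sub)
    palin <- sub == rc
    pd_f <- Biostrings::PDict(sub)
    pd_r <- Biostrings::PDict(rc)
    for (ch in names(seqs)) {
      subject <- seqs[[ch]]
      if (length(subject) < w) next
      for (str in c("+", "-")) {
        m <- Biostrings::matchPDict(if (str == "+") pd_f else pd_r, subject)
        cnt <- lengths(m)
        if (!sum(cnt)) next
        ir <- unlist(m)
        ki <- rep.int(seq_along(sub), cnt)
        keep <- if (str == "-") !palin[ki] else rep(TRUE, length(ki))
        if (!any(keep)) next
        recs[[length(recs) + 1L]] <- data.table::data.table(
          kmer_id = names(sub)[ki][keep], kmer = unname(sub[ki])[keep],
          chrom = ch, start = IRanges::start(ir)[keep],
          end = IRanges::end(ir)[keep], strand = str)
      }
    }
  }
  if (!length(recs)) return(empty)
  dt <- data.table::rbindlist(recs)
  dt[, strand := factor(strand, levels = c("+", "-"))]
  chrom_order <- names(seqs)
  dt[, chrom := factor(chrom, levels = chrom_order)]
  data.table::setorder(dt, kmer_id, chrom, start, strand)
  dt[, rank := seq_len(.N), by = "kmer_id"]
  dt[, truncated := .N > max_hits, by = "kmer_id"]
  dt <- dt[rank <= max_hits]
  gr <- GenomicRanges::GRanges(as.character(dt$chrom),
                               IRanges::IRanges(dt$start, dt$end),
                               strand = as.character(dt$strand))
  S4Vectors::mcols(gr)$kmer_id <- dt$kmer_id
  S4Vectors::mcols(gr)$kmer <- dt$kmer
  S4Vectors::mcols(gr)$truncated <- dt$truncated
  sl <- setNames(vapply(seqs, length, integer(1)), names(seqs))
  GenomeInfoDb::seqlengths(gr) <- sl[GenomeInfoDb::seqlevels(gr)]
  gr
}

#' Collapse a censat annotation name to its class
#'
#' The class is the substring before the first underscore, so
#' `"ct_1_1(p_arm)"` collapses to `"ct"`; names without an underscore are
#' returned whole.
#'
#' @param annotation_name character vector of censat-style names.
#' @return character vector of classes.
#' @examples
#' split_class(c("ct_1_1(p_arm)", "hor_1_1(S1C1H1L)", "arm"))
#' @export
split_class <- function(annotation_name) {
  if (any(!nzchar(annotation_name))) stop("empty annotation name")
  sub("_.*$", "", annotation_name)
}

#' Pivot k-mer mapping sites over annotation classes
#'
#' Each hit overlapping an annotation interval by at least 1 bp increments
#' the (k-mer, class) cell; a hit straddling a boundary counts once per
#' overlapped interval (the bedtools-intersect convention); hits entirely
#' outside the annotation are dropped.
#'
#' @param hits GRanges from [map_exact()] (needs a `kmer_id` column).
#' @param annotation GRanges with a `name` metadata column (censat-style).
#' @return integer matrix, rows = k-mer ids, columns = annotation classes;
#'   class `region_pivot`.
#' @export
pivot_regions <- function(hits, annotation) {
  stopifnot(is(hits, "GRanges"), is(annotation, "GRanges"))
  nm <- S4Vectors::mcols(annotation)$name
  if (is.null(nm)) stop("annotation needs a 'name' column")
  ov <- GenomicRanges::findOverlaps(hits, annotation, minoverlap = 1L,
                                    ignore.strand = TRUE)
  if (!length(ov)) {
    m <- matrix(integer(0), nrow = 0, ncol = 0)
    class(m) <- c("region_pivot", class(m))
    return(m)
  }
  dt <- data.table::data.table(
    kmer_id = S4Vectors::mcols(hits)$kmer_id[S4Vectors::queryHits(ov)],
    cls = split_class(nm[S4Vectors::subjectHits(ov)]))
  tab <- dt[, list(n = .N), by = c("kmer_id", "cls")]
  wide <- data.table::dcast(tab, kmer_id ~ cls, value.var = "n", fill = 0L)
  m <- as.matrix(wide, rownames = "kmer_id")
  storage.mode(m) <- "integer"
  class(m) <- c("region_pivot", class(m))
  m
}

#' Percentage of enriched k-mers mapping to each annotation class
#'
#' With the default `"any"` attribution a k-mer counts toward every class
#' it hits at least once, so percentages can sum above 100; with
#' `"majority"` each k-mer counts only toward its modal class (ties to the
#' alphabetically first). The denominator is the full enriched set by
#' default; `denominator = "mapped"` restricts it to enriched k-mers with
#' at least one in-annotation hit.
#'
#' @param pivot a `region_pivot` matrix.
#' @param enriched_set character vector of enriched k-mer ids.
#' @param attribution `"any"` or `"majority"`.
#' @param denominator `"all"` or `"mapped"`.
#' @return named numeric vector of percentages per class.
#' @export
region_percentages <- function(pivot, enriched_set,
                               attribution = c("any", "majority"),
                               denominator = c("all", "mapped")) {
  attribution <- match.arg(attribution)
  denominator <- match.arg(denominator)
  if (!length(enriched_set)) stop("enriched_set is empty")
  enriched_set <- as.character(enriched_set)
  classes <- colnames(pivot)
  if (is.null(classes)) return(setNames(numeric(0), character(0)))
  sub <- pivot[rownames(pivot) %in% enriched_set, , drop = FALSE]
  denom <- if (denominator == "all") length(enriched_set) else nrow(sub)
  if (denom == 0) stop("no enriched k-mers in denominator")
  if (attribution == "any") {
    n_per_class <- colSums(sub > 0)
  } else {
    n_per_class <- setNames(numeric(length(classes)), classes)
    if (nrow(sub)) {
      top <- classes[apply(sub, 1L, which.max)]
      tt <- table(top)
      n_per_class[names(tt)] <- as.numeric(tt)
    }
  }
  100 * n_per_class / denom
}

#' Write mapping hits as BED6
#' @param hits GRanges from [map_exact()].
#' @param path output path.
#' @return invisibly, the path.
#' @export
write_hits_bed <- function(hits, path) {
  dt <- data.table::data.table(
    chrom = as.character(GenomicRanges::seqnames(hits)),
    start = bed0_start(hits), end = GenomicRanges::end(hits),
    name = S4Vectors::mcols(hits)$kmer_id, score = 0L,
    strand = as.character(GenomicRanges::strand(hits)))
  data.table::fwrite(dt, path, sep = "\t", col.names = FALSE)
  invisible(path)
}

#' Per-base hit coverage as a bedGraph
#'
#' Genome-browser-style track of how many k-mer mapping sites cover each
#' base.
#'
#' @param hits GRanges from [map_exact()].
#' @param path output bedGraph path (optional).
#' @return data.table (chrom, start, end, coverage), 0-based half-open;
#'   written to `path` when given.
#' @export
hit_coverage <- function(hits, path = NULL) {
  cov <- GenomicRanges::coverage(hits)
  out <- data.table::rbindlist(lapply(names(cov), function(ch) {
    r <- cov[[ch]]
    ends <- cumsum(S4Vectors::runLength(r))
    data.table::data.table(chrom = ch,
                           start = c(0L, head(ends, -1L)), end = ends,
                           coverage = S4Vectors::runValue(r))
  }))
  out <- out[coverage > 0]
  if (!is.null(path)) data.table::fwrite(out, path, sep = "\t",
                                         col.names = FALSE)
  out
}
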