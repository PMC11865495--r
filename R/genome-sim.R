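## Toy repeat-genome simulator: a single chromosome laid out as unique arms,
## transition (ct) segments, monomeric and higher-order-repeat (HOR)
## alpha-satellite-like arrays, and human-satellite-like blocks, with a
## censat-style BED annotation covering the non-arm portion.

.CENSAT_CLASSES <- c("arm", "ct", "mon", "hor", "dhor", "hsat1", "hsat2")

#' Specify a toy repeat genome
#'
#' The segment plan is an ordered table of satellite classes. For `hor` and
#' `dhor` segments the `monomers` column gives the number of tandem monomer
#' copies (segment length is `monomers * monomer_length`); all other classes
#' take an explicit `length` in bp.
#'
#' @param segments data.frame with columns `class` (one of arm, ct, mon, hor,
#'   dhor, hsat1, hsat2), `length` (bp; `NA` for hor/dhor), `monomers`
#'   (monomer copies; `NA` unless hor/dhor) and optional `detail` (censat
#'   name suffix, e.g. `"p_arm"`). Defaults to [default_segment_plan()].
#' @param monomer_length alpha-satellite-like monomer length in bp.
#' @param hor_unit monomers per higher-order repeat unit: `hor` segments
#'   are tandem copies of a unit of `hor_unit` distinct seeded random
#'   monomers (each carrying the motif once), which is what makes an array
#'   a higher-order repeat; 1 reduces to tandem copies of a single
#'   monomer.
#' @param cenpb_motif IUPAC motif embedded once per HOR monomer. Degenerate
#'   (N) positions are resolved to concrete bases per genome under the seed.
#' @param seed integer seed; the same spec and seed give byte-identical
#'   output.
#' @param chrom chromosome name.
#' @return an object of class `genome_spec`.
#' @export
genome_spec <- function(segments = default_segment_plan(),
                        monomer_length = 171L,
                        hor_unit = 6L,
                        cenpb_motif = "NTTCGNNNNANNCGGGN",
                        seed = 1L,
                        chrom = "chrT") {
  segments <- as.data.frame(segments, stringsAsFactors = FALSE)
  if (is.null(segments$detail)) segments$detail <- ""
  segments$detail[is.na(segments$detail)] <- ""
  if (is.null(segments$monomers)) segments$monomers <- NA_real_
  if (!all(segments$class %in% .CENSAT_CLASSES))
    stop("segment classes must be among: ",
         paste(.CENSAT_CLASSES, collapse = ", "))
  tandem <- segments$class %in% c("hor", "dhor")
  if (any(tandem & (is.na(segments$monomers) | segments$monomers < 1)))
    stop("hor/dhor segments need a positive 'monomers' count")
  segments$length[tandem] <- segments$monomers[tandem] * monomer_length
  if (any(is.na(segments$length) | segments$length <= 0))
    stop("all segment lengths must be positive")
  if (monomer_length < nchar(cenpb_motif))
    stop("monomer_length must be >= motif length")
  if (!grepl("^[ACGTRYSWKMBDHVN]+$", cenpb_motif))
    stop("cenpb_motif must be IUPAC DNA")
  stopifnot_scalar_count(hor_unit, "hor_unit")
  structure(list(segments = segments,
                 monomer_length = as.integer(monomer_length),
                 hor_unit = as.integer(hor_unit),
                 cenpb_motif = cenpb_motif,
                 seed = as.integer(seed),
                 chrom = chrom),
            class = "genome_spec")
}

#' Default ~59.5 kb segment plan
#'
#' One centromere-like locus flanked by unique arms: p arm, p-arm transition,
#' Hsat1-like block, monomeric alpha-satellite, a 100-monomer HOR array (the
#' active-centromere stand-in), a short divergent HOR, an Hsat2-like block,
#' q-arm transition and q arm.
#'
#' @return data.frame usable as the `segments` argument of [genome_spec()].
#' @export
default_segment_plan <- function() {
  data.frame(
    class    = c("arm", "ct", "hsat1", "mon", "hor", "dhor", "hsat2", "ct",
                 "arm"),
    length   = c(10000, 4000, 5000, 2000, NA, NA, 5000, 4000, 10000),
    monomers = c(NA, NA, NA, NA, 100, 20, NA, NA, NA),
    detail   = c("", "p_arm", "", "", "S1C1H1L", "", "", "q_arm", ""),
    stringsAsFactors = FALSE
  )
}

## Resolve IUPAC degeneracies to concrete bases (uniform over the code's set).
resolve_iupac <- function(motif) {
  codes <- list(A = "A", C = "C", G = "G", T = "T",
                R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"),
                W = c("A", "T"), K = c("G", "T"), M = c("A", "C"),
                B = c("C", "G", "T"), D = c("A", "G", "T"),
                H = c("A", "C", "T"), V = c("A", "C", "G"),
                N = c("A", "C", "G", "T"))
  chars <- strsplit(motif, "")[[1]]
  paste(vapply(chars, function(ch) sample(codes[[ch]], 1L), ""),
        collapse = "")
}

## Tandem array of `unit`, truncated/extended to exactly `len` bases.
tandem_fill <- function(unit, len) {
  n <- ceiling(len / nchar(unit))
  substr(paste(rep(unit, n), collapse = ""), 1L, len)
}

## Point-mutate a fraction of positions of a sequence string.
mutate_seq <- function(s, rate) {
  if (rate <= 0) return(s)
  chars <- strsplit(s, "")[[1]]
  hit <- which(runif(length(chars)) < rate)
  if (length(hit)) {
    repl <- sample(c("A", "C", "G", "T"), length(hit), replace = TRUE)
    chars[hit] <- repl
  }
  paste(chars, collapse = "")
}

#' Build a toy repeat genome with censat-style annotation
#'
#' Assembles the chromosome segment by segment. HOR segments are tandem
#' copies of a higher-order unit of `hor_unit` distinct seeded random
#' monomers, each carrying the (resolved) CENP-B-box-like motif exactly
#' once; dhor segments are tandem monomer copies that diverge by ~2% point
#' mutations per copy; hsat blocks are tandem short units (AT-rich 42-mer
#' for hsat1, a 5-mer for hsat2); mon is a lightly shuffled monomer array;
#' arm and ct are unique random sequence, with two promoter-like 200 bp
#' windows recorded per ct segment. Annotation names follow the censat
#' convention `class_1_<counter>(<detail>)`, so the first p-arm transition
#' segment is named `ct_1_1(p_arm)`; arms are left unannotated.
#'
#' @param spec a [genome_spec()].
#' @return object of class `toy_genome`: list with `chrom`, `seq` (character),
#'   `annotation` (GRanges with `name` and `class`), `segments` (table with
#'   0-based coordinates), `features` (GRanges of promoter-like windows),
#'   `motif` (resolved concrete motif) and the `spec`.
#' @examples
#' g <- build_toy_genome(genome_spec(seed = 7))
#' nchar(g$seq)
#' head(g$annotation)
#' @export
build_toy_genome <- function(spec) {
  stopifnot(inherits(spec, "genome_spec"))
  seg <- spec$segments
  with_seed(spec$seed, {
    motif <- resolve_iupac(spec$cenpb_motif)
    pieces <- character(nrow(seg))
    feat_start0 <- integer(0); feat_end0 <- integer(0)
    for (i in seq_len(nrow(seg))) {
      cls <- seg$class[i]; len <- seg$length[i]
      pieces[i] <- switch(
        cls,
        arm = random_dna(len),
        ct = {
          s <- random_dna(len)
          off <- sum(nchar(pieces[seq_len(i - 1L)]))
          ## two promoter-like unique windows per transition segment
          pos <- sort(sample.int(len - 200L, 2L))
          pos[2] <- max(pos[2], pos[1] + 200L)
          feat_start0 <- c(feat_start0, off + pos)
          feat_end0 <- c(feat_end0, off + pos + 200L)
          s
        },
        mon = {
          unit <- random_dna(spec$monomer_length)
          n <- ceiling(len / spec$monomer_length)
          substr(paste(vapply(seq_len(n), function(j) mutate_seq(unit, 0.15),
                              ""), collapse = ""), 1L, len)
        },
        hor = {
          ## higher-order unit: hor_unit distinct monomers, one motif each
          unit_monos <- vapply(seq_len(spec$hor_unit), function(j) {
            mono <- random_dna(spec$monomer_length)
            off <- sample.int(spec$monomer_length - nchar(motif) + 1L, 1L)
            substr(mono, off, off + nchar(motif) - 1L) <- motif
            mono
          }, "")
          unit <- paste(unit_monos, collapse = "")
          tandem_fill(unit, seg$monomers[i] * spec$monomer_length)
        },
        dhor = {
          mono <- random_dna(spec$monomer_length)
          off <- sample.int(spec$monomer_length - nchar(motif) + 1L, 1L)
          substr(mono, off, off + nchar(motif) - 1L) <- motif
          paste(vapply(seq_len(seg$monomers[i]),
                       function(j) mutate_seq(mono, 0.02), ""),
                collapse = "")
        },
        hsat1 = tandem_fill(paste(sample(c("A", "T", "A", "T", "C", "G"),
                                         42L, replace = TRUE),
                                  collapse = ""), len),
        hsat2 = tandem_fill(random_dna(5L), len)
      )
    }
    genome_seq <- paste(pieces, collapse = "")
    seg$start0 <- cumsum(c(0, head(seg$length, -1)))
    seg$end0 <- seg$start0 + seg$length
    ann_rows <- which(seg$class != "arm")
    counter <- stats::ave(seq_along(ann_rows), seg$class[ann_rows],
                          FUN = seq_along)
    suffix <- ifelse(nzchar(seg$detail[ann_rows]),
                     paste0("(", seg$detail[ann_rows], ")"), "")
    nm <- sprintf("%s_1_%d%s", seg$class[ann_rows], counter, suffix)
    annotation <- granges_from_bed0(spec$chrom, seg$start0[ann_rows],
                                    seg$end0[ann_rows], name = nm)
    S4Vectors::mcols(annotation)$class <- seg$class[ann_rows]
    features <- granges_from_bed0(spec$chrom, feat_start0, feat_end0,
                                  name = rep("promoter",
                                             length(feat_start0)))
    sl <- nchar(genome_seq); names(sl) <- spec$chrom
    GenomeInfoDb::seqlengths(annotation) <- sl
    structure(list(chrom = spec$chrom, seq = genome_seq,
                   annotation = annotation, segments = seg,
                   features = features, motif = motif, spec = spec),
              class = "toy_genome")
  })
}

#' @export
print.toy_genome <- function(x, ...) {
  cat(sprintf("toy_genome: %s, %d bp, %d annotated segments (motif %s)\n",
              x$chrom, nchar(x$seq), length(x$annotation), x$motif))
  invisible(x)
}

#' Genome sequence as a DNAStringSet
#' @param genome a `toy_genome` or a named character vector of sequences.
#' @return DNAStringSet named by chromosome.
#' @export
genome_seqs <- function(genome) {
  if (inherits(genome, "toy_genome")) {
    out <- Biostrings::DNAStringSet(setNames(genome$seq, genome$chrom))
  } else if (is(genome, "DNAStringSet")) {
    out <- genome
  } else if (is.character(genome)) {
    out <- Biostrings::DNAStringSet(genome)
  } else stop("unsupported genome representation")
  out
}

#' Write a toy genome to FASTA and BED4
#'
#' @param genome a `toy_genome`.
#' @param dir output directory (created if needed).
#' @param prefix file name prefix.
#' @return invisibly, the paths written.
#' @export
write_genome <- function(genome, dir, prefix = "toy_genome") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  fa <- file.path(dir, paste0(prefix, ".fa"))
  bed <- file.path(dir, paste0(prefix, ".censat.bed"))
  Biostrings::writeXStringSet(genome_seqs(genome), fa)
  ann <- genome$annotation
  dt <- data.table::data.table(chrom = as.character(seqnames(ann)),
                               start = bed0_start(ann),
                               end = GenomicRanges::end(ann),
                               name = S4Vectors::mcols(ann)$name)
  data.table::fwrite(dt, bed, sep = "\t", col.names = FALSE)
  invisible(c(fasta = fa, bed = bed))
}

#' Read a BED4 annotation into a GRanges
#' @param path BED file (chrom, start, end, name; 0-based half-open).
#' @return GRanges with a `name` metadata column.
#' @export
read_annotation_bed <- function(path) {
  dt <- data.table::fread(path, header = FALSE)
  data.table::setnames(dt, seq_len(min(4L, ncol(dt))),
                       c("chrom", "start", "end", "name")[
                         seq_len(min(4L, ncol(dt)))])
  if (is.null(dt$name)) dt[, name := "."]
  granges_from_bed0(dt$chrom, dt$start, dt$end, name = dt$name)
}
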