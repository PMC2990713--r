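#' Default genome configuration
#'
#' Parameters of the synthetic diploid genome used throughout the package.
#' The defaults describe a compact multi-chromosome genome dense enough to
#' carry tens of planted CNVs of 50--500 Kb at the platform's probe spacing,
#' with merged gene intervals covering about 21\% of the sequence (the
#' genome-wide gene fraction of the rat assembly the pipeline is modeled on).
#'
#' @param chrom_lengths named numeric vector of chromosome lengths in bp.
#' @param gene_fraction target fraction of the genome covered by merged gene
#'   intervals, in \code{[0, 1]}.
#' @param gene_meanlog,gene_sdlog lognormal parameters (natural log of bp) for
#'   gene lengths.
#' @param n_ucsc,ucsc_min,ucsc_max count and length range (bp) of simulated
#'   ultraconserved elements.
#' @param n_mirna number of simulated miRNA loci (fixed ~90 bp hairpins).
#' @param n_qtl,qtl_min,qtl_max count and length range (bp) of simulated QTL
#'   intervals.
#' @return a list of class \code{genome_config}.
#' @export
genome_config <- function(chrom_lengths = setNames(rep(12e6, 8), paste0("chr", 1:8)),
                          gene_fraction = 0.21,
                          gene_meanlog = log(2e4), gene_sdlog = 0.6,
                          n_ucsc = 50, ucsc_min = 200, ucsc_max = 800,
                          n_mirna = 30,
                          n_qtl = 10, qtl_min = 5e5, qtl_max = 2e6) {
  cfg <- list(chrom_lengths = chrom_lengths, gene_fraction = gene_fraction,
              gene_meanlog = gene_meanlog, gene_sdlog = gene_sdlog,
              n_ucsc = n_ucsc, ucsc_min = ucsc_min, ucsc_max = ucsc_max,
              n_mirna = n_mirna, n_qtl = n_qtl, qtl_min = qtl_min, qtl_max = qtl_max)
  class(cfg) <- "genome_config"
  cfg
}

validate_genome_config <- function(config) {
  if (length(config$chrom_lengths) < 1L)
    stop("genome config needs at least one chromosome", call. = FALSE)
  if (is.null(names(config$chrom_lengths)) || anyDuplicated(names(config$chrom_lengths)))
    stop("chromosome names must be present and unique", call. = FALSE)
  if (any(config$chrom_lengths <= 0))
    stop("chromosome lengths must be positive", call. = FALSE)
  if (config$gene_fraction < 0 || config$gene_fraction > 1)
    stop("gene_fraction must lie in [0, 1]", call. = FALSE)
  invisible(config)
}

empty_features <- function() {
  data.frame(chrom = character(), start = numeric(), end = numeric(),
             id = character(), strand = character(), stringsAsFactors = FALSE)
}

# Uniform placement of one interval of length len; chromosome chosen with
# probability proportional to the number of valid start positions.
place_interval <- function(chrom_lengths, len) {
  valid <- pmax(chrom_lengths - len + 1, 0)
  if (all(valid == 0)) return(NULL)
  chrom <- sample(names(chrom_lengths), 1L, prob = valid)
  start <- floor(stats::runif(1, 0, valid[[chrom]]))
  data.frame(chrom = chrom, start = start, end = start + len, stringsAsFactors = FALSE)
}

#' Simulate a genome model with annotated feature interval sets
#'
#' Builds the reference the rest of the pipeline is tested against: ordered
#' chromosomes plus interval sets for genes, ultraconserved elements, miRNA
#' loci and QTLs. Genes are placed uniformly (overlaps allowed, as in real
#' annotation) until their merged coverage reaches the configured fraction of
#' the genome. All coordinates are 0-based, half-open.
#'
#' @param config a \code{\link{genome_config}}.
#' @param seed integer seed; output is deterministic for a fixed seed.
#' @return a \code{GenomeModel}: list with \code{chromosomes} (data.frame
#'   \code{chrom}, \code{length}) and \code{features} (named list of interval
#'   data.frames \code{genes}, \code{ucsc_elements}, \code{mirnas},
#'   \code{qtls}).
#' @export
make_genome <- function(config = genome_config(), seed = 1L) {
  validate_genome_config(config)
  set.seed(seed)
  cl <- config$chrom_lengths
  chromosomes <- data.frame(chrom = names(cl), length = unname(cl),
                            stringsAsFactors = FALSE)
  total <- sum(cl)

  genes <- empty_features()
  if (config$gene_fraction > 0) {
    target <- config$gene_fraction * total
    rows <- list(); covered <- 0; i <- 0L
    while (covered < target) {
      i <- i + 1L
      len <- min(round(stats::rlnorm(1, config$gene_meanlog, config$gene_sdlog)),
                 max(cl) - 1)
      len <- max(len, 200)
      iv <- place_interval(cl, len)
      rows[[i]] <- iv
      # recompute merged coverage periodically; overshoot is at most a few genes
      if (i %% 16L == 0L)
        covered <- merged_length_df(do.call(rbind, rows))
    }
    genes <- do.call(rbind, rows)
    genes$id <- sprintf("gene%05d", seq_len(nrow(genes)))
    genes$strand <- sample(c("+", "-"), nrow(genes), replace = TRUE)
  }

  # features whose lengths exceed every chromosome are silently dropped, so
  # small toy genomes need not carry QTL-scale intervals
  make_set <- function(n, len_fun, prefix, stranded = FALSE) {
    if (n == 0L) return(empty_features())
    rows <- lapply(seq_len(n), function(i) place_interval(cl, len_fun()))
    rows <- rows[!vapply(rows, is.null, logical(1))]
    if (length(rows) == 0L) return(empty_features())
    out <- do.call(rbind, rows)
    out$id <- sprintf("%s%04d", prefix, seq_len(nrow(out)))
    out$strand <- if (stranded) sample(c("+", "-"), nrow(out), replace = TRUE) else "."
    out
  }
  ucsc <- make_set(config$n_ucsc,
                   function() round(stats::runif(1, config$ucsc_min, config$ucsc_max)),
                   "uc.")
  mirnas <- make_set(config$n_mirna, function() 90, "mir-", stranded = TRUE)
  qtls <- make_set(config$n_qtl,
                   function() round(stats::runif(1, config$qtl_min, config$qtl_max)),
                   "qtl")

  genome <- list(chromosomes = chromosomes,
                 features = list(genes = genes, ucsc_elements = ucsc,
                                 mirnas = mirnas, qtls = qtls))
  class(genome) <- "GenomeModel"
  genome
}

#' @export
print.GenomeModel <- function(x, ...) {
  cat("GenomeModel:", nrow(x$chromosomes), "chromosomes,",
      format(sum(x$chromosomes$length), big.mark = ","), "bp\n")
  for (nm in names(x$features))
    cat("  ", nm, ": ", nrow(x$features[[nm]]), " intervals\n", sep = "")
  invisible(x)
}

chrom_length <- function(genome, chrom) {
  i <- match(chrom, genome$chromosomes$chrom)
  if (anyNA(i)) stop("unknown chromosome: ", paste(chrom[is.na(i)], collapse = ", "),
                     call. = FALSE)
  genome$chromosomes$length[i]
}

#' Plant gain and loss CNVs into per-sample truth sets
#'
#' Places non-overlapping copy-number variants (copy state 1 or 3 against the
#' diploid baseline 2) for each sample. A configurable fraction of each
#' sample's CNVs is shared identically by all samples, emulating the
#' cross-individual consistency seen in inbred-strain comparisons; the rest
#' are private to one sample. Homozygous deletions (copy 0) are not modeled.
#'
#' @param genome a \code{GenomeModel}.
#' @param n_per_sample CNVs per sample (>= 0).
#' @param samples character vector of sample ids.
#' @param length_range numeric length-2: uniform CNV length range in bp.
#' @param shared_fraction fraction (rounded to a count) of each sample's CNVs
#'   shared by all samples.
#' @param gain_fraction fraction of CNVs that are gains (copy 3).
#' @param seed integer seed.
#' @param max_tries placement retries before giving up.
#' @return a \code{TruthSet}: data.frame with \code{chrom}, \code{start},
#'   \code{end}, \code{copy_state}, \code{cnv_id}, \code{sample_id} (one row
#'   per CNV-sample assignment; shared CNVs repeat across samples with the
#'   same \code{cnv_id}).
#' @export
plant_cnvs <- function(genome, n_per_sample = 40L,
                       samples = c("GK1", "GK2", "GK3"),
                       length_range = c(5e4, 5e5),
                       shared_fraction = 0.7, gain_fraction = 0.5,
                       seed = 1L, max_tries = 1000L) {
  stopifnot(n_per_sample >= 0, shared_fraction >= 0, shared_fraction <= 1)
  set.seed(seed)
  out <- data.frame(chrom = character(), start = numeric(), end = numeric(),
                    copy_state = integer(), cnv_id = character(),
                    sample_id = character(), stringsAsFactors = FALSE)
  class(out) <- c("TruthSet", "data.frame")
  attr(out, "samples") <- samples
  if (n_per_sample == 0L) return(out)

  cl <- stats::setNames(genome$chromosomes$length, genome$chromosomes$chrom)
  n_shared <- round(shared_fraction * n_per_sample)
  n_private <- n_per_sample - n_shared

  # occupied intervals per sample, to keep each sample's CNVs disjoint
  occ <- stats::setNames(replicate(length(samples), list(), simplify = FALSE), samples)
  overlaps_any <- function(iv, lst) {
    for (o in lst)
      if (o$chrom == iv$chrom && iv$start < o$end && o$start < iv$end) return(TRUE)
    FALSE
  }
  draw_cnv <- function(block_samples) {
    for (t in seq_len(max_tries)) {
      len <- round(stats::runif(1, length_range[1], length_range[2]))
      iv <- place_interval(cl, len)
      if (is.null(iv)) break
      if (!any(vapply(block_samples, function(s) overlaps_any(iv, occ[[s]]), logical(1))))
        return(iv)
    }
    stop("could not place a CNV without overlap after ", max_tries,
         " tries; genome too small", call. = FALSE)
  }

  rows <- list(); k <- 0L
  add <- function(iv, state, id, sids) {
    for (s in sids) occ[[s]][[length(occ[[s]]) + 1L]] <<- iv
    k <<- k + 1L
    rows[[k]] <<- data.frame(chrom = iv$chrom, start = iv$start, end = iv$end,
                             copy_state = state, cnv_id = id, sample_id = sids,
                             stringsAsFactors = FALSE)
  }
  state_of <- function(i) if (stats::runif(1) < gain_fraction) 3L else 1L

  for (i in seq_len(n_shared)) {
    iv <- draw_cnv(samples)
    add(iv, state_of(i), sprintf("cnv_shared_%03d", i), samples)
  }
  for (s in samples) for (i in seq_len(n_private)) {
    iv <- draw_cnv(s)
    add(iv, state_of(i), sprintf("cnv_%s_%03d", s, i), s)
  }
  out <- do.call(rbind, rows)
  class(out) <- c("TruthSet", "data.frame")
  attr(out, "samples") <- samples
  out
}

#' Tile probes along the genome and assign chip grid positions
#'
#' Lays fixed-length probes along each chromosome with jittered spacing whose
#' median matches \code{target_spacing} (the platform emulated has a 7.9 Kb
#' median spacing), then assigns grid positions row-major over a near-square
#' chip. Optionally a fraction of probes is duplicated as on-chip replicates
#' measuring the same locus.
#'
#' @param genome a \code{GenomeModel}.
#' @param target_spacing target median inter-probe spacing, bp.
#' @param probe_length probe length, bp (must be < \code{target_spacing}).
#' @param replicate_fraction fraction of loci duplicated as replicate spots.
#' @param seed integer seed.
#' @return a \code{ChipLayout}: data.frame \code{probe_id}, \code{chrom},
#'   \code{start}, \code{end}, \code{grid_row}, \code{grid_col},
#'   \code{locus_id} (shared by replicate spots), sorted by (chrom, start)
#'   with replicates scattered over the grid.
#' @export
tile_probes <- function(genome, target_spacing = 7900, probe_length = 60,
                        replicate_fraction = 0, seed = 1L) {
  if (target_spacing <= probe_length)
    stop("target_spacing must exceed probe_length", call. = FALSE)
  set.seed(seed)
  rows <- list()
  for (i in seq_len(nrow(genome$chromosomes))) {
    chrom <- genome$chromosomes$chrom[i]
    len <- genome$chromosomes$length[i]
    if (len < probe_length) next
    pos <- floor(stats::runif(1, 0, min(target_spacing, len - probe_length + 1)))
    starts <- numeric(0)
    while (pos + probe_length <= len) {
      starts <- c(starts, pos)
      # jitter keeps the median gap at the target while varying spacing
      pos <- pos + round(target_spacing * stats::runif(1, 0.75, 1.25))
    }
    if (length(starts) == 0) starts <- 0
    rows[[i]] <- data.frame(chrom = chrom, start = starts,
                            end = starts + probe_length, stringsAsFactors = FALSE)
  }
  probes <- do.call(rbind, rows)
  probes <- probes[order(match(probes$chrom, genome$chromosomes$chrom), probes$start), ]
  probes$locus_id <- sprintf("locus%06d", seq_len(nrow(probes)))

  if (replicate_fraction > 0) {
    ndup <- round(replicate_fraction * nrow(probes))
    dup <- probes[sample.int(nrow(probes), ndup), , drop = FALSE]
    probes <- rbind(probes, dup)
    probes <- probes[order(match(probes$chrom, genome$chromosomes$chrom), probes$start), ]
  }
  n <- nrow(probes)
  probes$probe_id <- sprintf("probe%06d", seq_len(n))
  # grid assignment is independent of genomic order, as on a real chip
  ncol <- ceiling(sqrt(n))
  perm <- sample.int(n)
  probes$grid_row <- ((perm - 1L) %/% ncol) + 1L
  probes$grid_col <- ((perm - 1L) %% ncol) + 1L
  rownames(probes) <- NULL
  probes <- probes[, c("probe_id", "chrom", "start", "end",
                       "grid_row", "grid_col", "locus_id")]
  class(probes) <- c("ChipLayout", "data.frame")
  probes
}

#' Median inter-probe spacing of a layout
#' @param layout a \code{ChipLayout}.
#' @return median distance between consecutive probe starts, bp.
#' @export
median_spacing <- function(layout) {
  gaps <- unlist(lapply(split(layout$start, layout$chrom),
                        function(s) diff(sort(unique(s)))))
  stats::median(gaps)
}
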