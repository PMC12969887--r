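#' Derive a per-stage child seed from one global seed
#'
#' Every generator in the package takes its own integer seed; pipelines
#' that run several generators expand one global seed into per-stage
#' child seeds with this fixed mapping, so a single integer reproduces a
#' whole fixture set. Stage offsets: te_annotation 1, peaks 2 (plus a
#' dataset index), polya 3, expression 4, cnv 5, isoforms 6.
#'
#' @param seed global integer seed.
#' @param stage stage name (see above) or an integer offset.
#' @param index optional extra index (e.g. peak dataset number).
#' @return integer child seed in `[0, 2^31)`.
#' @export
child_seed <- function(seed, stage, index = 0L) {
  offsets <- c(te_annotation = 1L, peaks = 2L, polya = 3L,
               expression = 4L, cnv = 5L, isoforms = 6L)
  off <- if (is.character(stage)) {
    if (!stage %in% names(offsets)) stop("unknown stage: ", stage)
    offsets[[stage]]
  } else as.integer(stage)
  as.integer((as.numeric(seed) * 7919 + off * 101 + index) %% 2147483647)
}

# Internal: substitute bases i.i.d. at rate `rate`; never a silent change.
.mutate_seq <- function(seq, rate) {
  if (rate <= 0) return(seq)
  bases <- c("A", "C", "G", "T")
  chars <- strsplit(seq, "")[[1]]
  hit <- which(stats::runif(length(chars)) < rate)
  for (i in hit) {
    chars[i] <- sample(setdiff(bases, chars[i]), 1)
  }
  paste(chars, collapse = "")
}

# Internal: remove every occurrence of `motif` by substituting its middle
# base, looping until the sequence is motif-free.
.scrub_motif <- function(seq, motif = "AATAAA") {
  repeat {
    m <- regexpr(motif, seq, fixed = TRUE)
    if (m < 0) return(seq)
    pos <- as.integer(m) + 2L           # middle 'T' of AATAAA
    cur <- substr(seq, pos, pos)
    repl <- if (cur == "G") "C" else "G"
    substr(seq, pos, pos) <- repl
  }
}

# Internal: place k non-overlapping widths on a chromosome of length L by
# distributing the free space uniformly; returns sorted 0-based starts.
.place_nonoverlapping <- function(widths, L) {
  k <- length(widths)
  if (!k) return(integer())
  free <- L - sum(widths)
  if (free < 0) return(NULL)
  off <- sort(floor(stats::runif(k, 0, free + 1)))
  as.integer(off + cumsum(c(0, widths))[seq_len(k)])
}

#' Simulate a TE annotation with per-family consensus sequences
#'
#' Places non-overlapping repeat instances of several families on a small
#' synthetic genome. Each family gets a fixed instance width drawn from
#' `width_range` and a random consensus sequence of that width; instance
#' sequences are the consensus with i.i.d. substitutions at the family
#' divergence rate. Strands are assigned uniformly.
#'
#' @param genome named numeric vector of chromosome lengths (bp).
#' @param families character vector of family names, or a single count
#'   (names are then `FAM01`, `FAM02`, ...).
#' @param instances_per_family single count or named vector per family;
#'   a family with 0 requested instances stays in the registry but is
#'   absent from the output intervals.
#' @param width_range instance width range in bp, default `c(200, 400)`.
#' @param divergence substitution rate applied to instance sequences,
#'   default 0.1.
#' @param seed integer seed; fixed seed gives identical output.
#' @return list with `instances` (interval data.frame with `family`,
#'   `id`, `divergence`), `sequences` (named character, instance
#'   sequences), `consensi` (named character, per family), `families`
#'   (registry data.frame), `genome`.
#' @export
simulate_te_annotation <- function(genome, families, instances_per_family,
                                   width_range = c(200, 400),
                                   divergence = 0.1, seed = 1) {
  if (is.null(names(genome))) stop("genome must be a named length vector")
  if (length(families) == 1 && is.numeric(families))
    families <- sprintf("FAM%02d", seq_len(families))
  n_fam <- length(families)
  counts <- if (length(instances_per_family) == 1)
    stats::setNames(rep(instances_per_family, n_fam), families)
  else {
    if (is.null(names(instances_per_family)) ||
        !all(families %in% names(instances_per_family)))
      stop("instances_per_family must be a count or named per family")
    instances_per_family[families]
  }
  set.seed(seed)
  widths <- stats::setNames(
    as.integer(round(stats::runif(n_fam, width_range[1], width_range[2]))),
    families)
  bases <- c("A", "C", "G", "T")
  consensi <- stats::setNames(vapply(families, function(f) {
    .scrub_motif(paste(sample(bases, widths[[f]], replace = TRUE),
                       collapse = ""))
  }, ""), families)

  total_bp <- sum(widths[families] * counts[families])
  if (total_bp > 0.5 * sum(genome))
    stop("genome too small: placing ", total_bp,
         " bp of TEs needs a genome of at least ", 2 * total_bp, " bp")

  fam_of <- rep(families, times = counts[families])
  if (!length(fam_of)) {
    inst <- data.frame(chrom = character(), start = integer(),
                       end = integer(), strand = character(),
                       family = character(), id = character(),
                       divergence = numeric())
    return(list(instances = inst, sequences = character(),
                consensi = consensi,
                families = data.frame(family = families,
                                      width = unname(widths[families]),
                                      n_requested = unname(counts[families])),
                genome = genome))
  }
  chrom_of <- sample(names(genome), length(fam_of), replace = TRUE,
                     prob = genome / sum(genome))
  rows <- list()
  for (ch in names(genome)) {
    idx <- which(chrom_of == ch)
    if (!length(idx)) next
    w <- widths[fam_of[idx]]
    ord <- sample(length(idx))   # random interleaving of families
    starts <- .place_nonoverlapping(unname(w[ord]), genome[[ch]])
    if (is.null(starts))
      stop("genome too small: chromosome ", ch, " cannot hold ",
           sum(w), " bp of TEs")
    rows[[ch]] <- data.frame(
      chrom = ch, start = starts, end = starts + unname(w[ord]),
      strand = sample(c("+", "-"), length(idx), replace = TRUE),
      family = fam_of[idx][ord], stringsAsFactors = FALSE)
  }
  inst <- do.call(rbind, rows)
  rownames(inst) <- NULL
  inst$id <- stats::ave(seq_len(nrow(inst)), inst$family,
                        FUN = seq_along)
  inst$id <- paste0(inst$family, "_", inst$id)
  inst$divergence <- divergence * 100   # percent, RepeatMasker-style
  seqs <- stats::setNames(vapply(seq_len(nrow(inst)), function(i) {
    .mutate_seq(consensi[[inst$family[i]]], divergence)
  }, ""), inst$id)
  list(instances = inst, sequences = seqs, consensi = consensi,
       families = data.frame(family = families,
                             width = unname(widths[families]),
                             n_requested = unname(counts[families])),
       genome = genome)
}

#' Simulate a ChIP-seq-like peak set with planted family enrichment
#'
#' Background peaks are placed uniformly over the genome. For each family
#' named in `enrichment`, the placement density over that family's
#' genomic footprint is multiplied by its fold (renormalized), so the
#' expected fraction of its instances overlapped by a peak increases
#' monotonically with the fold. An empty fold map gives the uniform null.
#'
#' @param te `instances` data.frame from [simulate_te_annotation()].
#' @param genome named chromosome length vector.
#' @param dataset_name label stored in the `dataset` column.
#' @param n_peaks number of peaks.
#' @param enrichment named numeric vector of folds (all `>= 1`) keyed by
#'   family name; families must exist in `te`.
#' @param mean_width mean peak width, default 400 bp.
#' @param seed integer seed.
#' @return peak data.frame (chrom, start, end, strand, signal, dataset,
#'   id).
#' @export
simulate_peakset <- function(te, genome, dataset_name, n_peaks,
                             enrichment = numeric(), mean_width = 400,
                             seed = 1) {
  if (length(enrichment)) {
    if (any(enrichment < 1)) stop("enrichment folds must be >= 1")
    unknown <- setdiff(names(enrichment), unique(te$family))
    if (length(unknown))
      stop("fold given for unknown family: ",
           paste(unknown, collapse = ", "))
  }
  empty <- data.frame(chrom = character(), start = integer(),
                      end = integer(), strand = character(),
                      signal = numeric(), dataset = character(),
                      id = character())
  if (n_peaks == 0) return(empty)
  set.seed(seed)
  G <- sum(genome)
  fams <- names(enrichment)
  fp <- vapply(fams, function(f) {
    sub <- te[te$family == f, , drop = FALSE]
    sum(sub$end - sub$start)
  }, 0)
  extra <- (enrichment - 1) * fp
  W <- G + sum(extra)
  comp <- sample(c("bg", fams), n_peaks, replace = TRUE,
                 prob = c(G, extra) / W)
  widths <- pmax(50L, as.integer(round(
    stats::rnorm(n_peaks, mean_width, mean_width / 4))))
  centers <- integer(n_peaks)
  chroms <- character(n_peaks)
  bg <- comp == "bg"
  if (any(bg)) {
    chroms[bg] <- sample(names(genome), sum(bg), replace = TRUE,
                         prob = genome / sum(genome))
    centers[bg] <- as.integer(floor(
      stats::runif(sum(bg)) * genome[chroms[bg]]))
  }
  for (f in fams) {
    idx <- which(comp == f)
    if (!length(idx)) next
    sub <- te[te$family == f, , drop = FALSE]
    pick <- sample(nrow(sub), length(idx), replace = TRUE,
                   prob = sub$end - sub$start)
    chroms[idx] <- sub$chrom[pick]
    centers[idx] <- as.integer(floor(
      sub$start[pick] + stats::runif(length(idx)) *
        (sub$end[pick] - sub$start[pick])))
  }
  start <- pmax(0L, centers - widths %/% 2L)
  end <- pmin(as.integer(genome[chroms]), start + widths)
  start <- pmax(0L, pmin(start, end - 1L))
  data.frame(chrom = chroms, start = start, end = end, strand = ".",
             signal = round(stats::rgamma(n_peaks, shape = 2, scale = 5), 3),
             dataset = dataset_name,
             id = paste0(dataset_name, "_peak", seq_len(n_peaks)),
             stringsAsFactors = FALSE)
}

#' Simulate diverged repeat windows with a planted polyA hexamer
#'
#' Builds (or accepts) a family consensus that carries no `AATAAA`, then
#' draws instance windows as diverged substrings of it: each instance
#' takes a random offset (constrained so the plant position stays inside
#' the window), receives i.i.d. substitutions at the divergence rate, has
#' any accidental `AATAAA` scrubbed, and — with probability `plant_rate`
#' — gets the exact hexamer written at the consensus-coordinate position
#' `hexamer_pos`. The substitution-only model makes the instance-to-
#' consensus truth alignment unambiguous (instance position `i` maps to
#' consensus position `offset + i`).
#'
#' @param consensus_seq consensus DNA string of length `>= window`, or
#'   `NULL` to generate a random scrubbed consensus of `consensus_len`.
#' @param n_instances number of instance windows.
#' @param divergence substitution rate in `[0, 1)`.
#' @param plant_rate probability that an instance carries the hexamer.
#' @param exact if TRUE, plant in exactly `round(plant_rate *
#'   n_instances)` instances (chosen at random) instead of i.i.d.
#'   Bernoulli draws; used for fixed designs like 12-of-14.
#' @param hexamer_pos 0-based plant position on the consensus; default
#'   places it 80 bp before the consensus end.
#' @param seed integer seed.
#' @param window window length, default 200.
#' @param consensus_len length of a generated consensus, default 300.
#' @return list with `sequences` (named character windows), `truth`
#'   (data.frame: id, planted, offset, hexamer_window_pos, consensus
#'   plant position), `consensus`, `hexamer_pos`, `window`.
#' @export
simulate_polya_instances <- function(consensus_seq = NULL, n_instances,
                                     divergence, plant_rate,
                                     hexamer_pos = NULL, seed = 1,
                                     window = 200, consensus_len = 300,
                                     exact = FALSE) {
  stopifnot(plant_rate >= 0, plant_rate <= 1, divergence >= 0,
            divergence < 1)
  set.seed(seed)
  if (is.null(consensus_seq)) {
    consensus_seq <- .scrub_motif(paste(
      sample(c("A", "C", "G", "T"), consensus_len, replace = TRUE),
      collapse = ""))
  } else {
    consensus_seq <- chartr("U", "T", toupper(consensus_seq))
    consensus_seq <- .scrub_motif(consensus_seq)
  }
  L <- nchar(consensus_seq)
  if (L < window)
    stop("consensus shorter than the window (", L, " < ", window, ")")
  if (is.null(hexamer_pos)) hexamer_pos <- L - 80L
  if (hexamer_pos < 0 || hexamer_pos + 6 > L)
    stop("hexamer_pos + 6 must lie within the consensus")
  o_lo <- max(0L, hexamer_pos + 6L - window)
  o_hi <- min(hexamer_pos, L - window)
  if (o_lo > o_hi)
    stop("no window offset can contain the plant position")
  ids <- sprintf("inst%02d", seq_len(n_instances))
  offs <- if (o_hi > o_lo)
    as.integer(floor(stats::runif(n_instances, o_lo, o_hi + 1)))
  else rep(o_lo, n_instances)
  offs <- pmin(offs, o_hi)
  planted <- if (exact) {
    k <- round(plant_rate * n_instances)
    seq_len(n_instances) %in% sample(n_instances, k)
  } else stats::runif(n_instances) < plant_rate
  seqs <- character(n_instances)
  nsub <- integer(n_instances)
  for (i in seq_len(n_instances)) {
    s0 <- substr(consensus_seq, offs[i] + 1L, offs[i] + window)
    s <- .mutate_seq(s0, divergence)
    s <- .scrub_motif(s)
    if (planted[i]) {
      p <- hexamer_pos - offs[i]           # 0-based within window
      substr(s, p + 1L, p + 6L) <- "AATAAA"
    }
    nsub[i] <- sum(strsplit(s0, "")[[1]] != strsplit(s, "")[[1]])
    seqs[i] <- s
  }
  names(seqs) <- ids
  list(sequences = seqs,
       truth = data.frame(id = ids, planted = planted, offset = offs,
                          hexamer_window_pos = ifelse(
                            planted, hexamer_pos - offs, NA_integer_),
                          hexamer_consensus_pos = ifelse(
                            planted, hexamer_pos, NA_integer_),
                          n_sub = nsub, stringsAsFactors = FALSE),
       consensus = consensus_seq, hexamer_pos = hexamer_pos,
       window = window)
}

#' Simulate an expression matrix with a planted two-TF dosage effect
#'
#' On the latent log2 scale, the two designated TF genes are i.i.d.
#' standard normal per sample; the target gene is
#' `a * z(TF1) + b * z(TF2) + Normal(0, sigma)`; all remaining genes are
#' i.i.d. noise. Raw values are `2^latent`, mimicking TPM, so the
#' pipeline's log2 transform recovers the latent scale exactly.
#'
#' @param n_genes,n_samples matrix dimensions (`n_samples >= 4`).
#' @param a,b additive effect sizes of the two TFs on the target.
#' @param sigma residual sd on the target (`>= 0`).
#' @param seed integer seed.
#' @param tf1,tf2,target row names of the planted genes.
#' @return list with `raw` and `latent` gene-by-sample matrices and a
#'   `truth` record of the planted parameters.
#' @export
simulate_expression <- function(n_genes, n_samples, a, b, sigma, seed = 1,
                                tf1 = "TF1", tf2 = "TF2",
                                target = "TARGET") {
  if (sigma < 0) stop("sigma must be >= 0")
  if (n_samples < 4) stop("need n_samples >= 4")
  if (n_genes < 3) stop("need n_genes >= 3")
  set.seed(seed)
  genes <- c(tf1, tf2, target,
             sprintf("G%04d", seq_len(max(0, n_genes - 3))))
  latent <- matrix(stats::rnorm(n_genes * n_samples), nrow = n_genes,
                   dimnames = list(genes,
                                   sprintf("S%02d", seq_len(n_samples))))
  # the planted effect acts on the per-sample Z scores, matching the
  # dosage statistic's additive model
  latent[target, ] <- a * zscore(latent[tf1, ]) +
    b * zscore(latent[tf2, ]) + stats::rnorm(n_samples, 0, sigma)
  list(raw = 2^latent, latent = latent,
       truth = list(tf1 = tf1, tf2 = tf2, target = target,
                    a = a, b = b, sigma = sigma))
}

#' Simulate a per-sample CNV table over a locus window
#'
#' Per sample, loss and gain event counts are Poisson with group-specific
#' rates; event sizes are uniform in `size_range`; every event lies
#' inside the locus window.
#'
#' @param groups data.frame with columns `group`, `n_samples`,
#'   `loss_rate`, `gain_rate` (per-sample Poisson means).
#' @param locus_window one-row interval data.frame (chrom, start, end).
#' @param size_range event size range in bp, minimum `>= 1`.
#' @param seed integer seed.
#' @return data.frame (sample, group, chrom, start, end, type, size);
#'   zero rows when all rates are 0.
#' @export
simulate_cnv_table <- function(groups, locus_window,
                               size_range = c(1000, 50000), seed = 1) {
  if (!is.data.frame(groups) || !nrow(groups))
    stop("groups must be a non-empty data.frame")
  stopifnot(all(c("group", "n_samples", "loss_rate", "gain_rate") %in%
                  names(groups)),
            size_range[1] >= 1)
  validate_intervals(locus_window, "locus_window")
  set.seed(seed)
  wlen <- locus_window$end[1] - locus_window$start[1]
  size_range[2] <- min(size_range[2], wlen)
  rows <- list()
  for (g in seq_len(nrow(groups))) {
    for (s in seq_len(groups$n_samples[g])) {
      sid <- sprintf("%s_s%03d", groups$group[g], s)
      for (type in c("loss", "gain")) {
        rate <- groups[[paste0(type, "_rate")]][g]
        k <- stats::rpois(1, rate)
        if (!k) next
        size <- as.integer(round(stats::runif(k, size_range[1],
                                              size_range[2])))
        start <- as.integer(floor(locus_window$start[1] +
          stats::runif(k) * (wlen - size)))
        rows[[length(rows) + 1]] <- data.frame(
          sample = sid, group = groups$group[g],
          chrom = locus_window$chrom[1], start = start,
          end = start + size, type = type, size = size,
          stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(rows))
    return(data.frame(sample = character(), group = character(),
                      chrom = character(), start = integer(),
                      end = integer(), type = character(),
                      size = integer()))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Roster of simulated CNV samples
#'
#' Companion to [simulate_cnv_table()]: the full sample/group roster,
#' including samples that drew zero events (the burden test needs them).
#'
#' @param groups the same `groups` data.frame.
#' @return data.frame (sample, group).
#' @export
cnv_sample_roster <- function(groups) {
  do.call(rbind, lapply(seq_len(nrow(groups)), function(g) {
    data.frame(sample = sprintf("%s_s%03d", groups$group[g],
                                seq_len(groups$n_samples[g])),
               group = groups$group[g], stringsAsFactors = FALSE)
  }))
}

#' Simulate a membrane/secreted isoform protein pair
#'
#' Emulates an alternative-polyadenylation isoform pair: both proteins
#' share a hydrophilic core; the membrane isoform additionally carries a
#' hydrophobic C-terminal tail (poly-leucine by default) long enough to
#' be called as a transmembrane segment.
#'
#' @param core_len shared core length in residues, default 120.
#' @param tail_len hydrophobic tail length, default 25.
#' @param seed integer seed.
#' @return list with `membrane` and `secreted` amino-acid strings.
#' @export
simulate_isoform_pair <- function(core_len = 120, tail_len = 25,
                                  seed = 1) {
  set.seed(seed)
  hydrophilic <- c("D", "E", "K", "R", "N", "Q", "S", "T", "G", "P", "H")
  core <- paste(sample(hydrophilic, core_len, replace = TRUE),
                collapse = "")
  list(membrane = paste0(core, strrep("L", tail_len)), secreted = core)
}
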