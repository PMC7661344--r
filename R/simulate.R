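# Per-generator RNG streams: each generator derives its own seed from
# (user seed, generator tag), so adding a generator call to a script
# never perturbs the output of the others.
.derive_seed <- function(seed, tag) {
  stopifnot(is.numeric(seed), length(seed) == 1, is.finite(seed))
  h <- 0
  for (ch in utf8ToInt(tag)) h <- (h * 131 + ch) %% 1009
  as.integer((abs(seed) %% 2e6) * 1009 + h)
}

#' Simulate non-overlapping stranded gene models
#'
#' Places `n_genes` genes on the given chromosomes with all pairwise
#' gaps of at least `min_gap` bp (default 4000, so the 2-kb promoter
#' and downstream flanks of adjacent genes can never overlap) and a
#' 2.5-kb margin from chromosome ends. Each gene gets a random strand
#' and 1 to `max_exons` exons partitioning its body (first and last
#' exon anchored at the gene ends). Identical parameters and seed give
#' identical output.
#'
#' @param n_genes Number of genes (>= 0).
#' @param chrom_lengths Named numeric vector of chromosome lengths
#'   (each > 10 kb).
#' @param min_gap Minimum gap between gene bodies in bp (>= 4000).
#' @param gene_length Length range `c(lo, hi)` for gene bodies.
#' @param max_exons Maximum exons per gene.
#' @param seed Integer seed.
#' @return Gene-model tibble: `gene_id`, `chrom`, `strand`, `start`,
#'   `end`, `tss`, `tes`, `exons` (list of `tibble(start, end)`).
#' @export
sim_gene_models <- function(n_genes, chrom_lengths, min_gap = 4000,
                            gene_length = c(2000, 10000), max_exons = 5,
                            seed = 1) {
  stopifnot(n_genes >= 0, all(chrom_lengths > 10000), min_gap >= 4000,
            length(gene_length) == 2, gene_length[1] >= 3,
            gene_length[1] <= gene_length[2], max_exons >= 1)
  empty <- tibble(gene_id = character(), chrom = character(),
                  strand = character(), start = numeric(), end = numeric(),
                  tss = numeric(), tes = numeric(), exons = list())
  if (n_genes == 0) return(empty)

  margin <- 2500
  cap <- floor((chrom_lengths - 2 * margin + min_gap) /
                 (gene_length[2] + min_gap))
  cap <- pmax(0, cap)
  if (sum(cap) < n_genes) {
    abort(sprintf(
      "Insufficient genome space: capacity %d genes at min_gap %d, requested %d.",
      sum(cap), min_gap, n_genes
    ))
  }
  # deterministic proportional allocation of genes to chromosomes
  share <- n_genes * cap / sum(cap)
  n_c <- pmin(cap, floor(share))
  while (sum(n_c) < n_genes) {
    room <- cap - n_c
    i <- which(room > 0)[which.max((share - n_c)[room > 0])]
    n_c[i] <- n_c[i] + 1
  }

  withr::with_seed(.derive_seed(seed, "genes"), {
    gid <- 0L
    rows <- purrr::map_dfr(seq_along(chrom_lengths), function(ci) {
      n <- n_c[ci]
      if (n == 0) return(NULL)
      len <- chrom_lengths[ci]
      L <- sample(seq(gene_length[1], gene_length[2]), n, replace = TRUE)
      slack <- (len - 2 * margin) - sum(L) - (n - 1) * min_gap
      cuts <- if (n > 1) sort(runif(n - 1)) else numeric(0)
      parts <- floor(diff(c(0, cuts, 1)) * slack)
      pos <- margin + 1
      purrr::map_dfr(seq_len(n), function(i) {
        start <- pos + parts[i]
        end <- start + L[i] - 1
        pos <<- end + 1 + min_gap
        strand <- sample(c("+", "-"), 1)
        n_ex <- sample.int(max_exons, 1)
        n_ex <- min(n_ex, floor((L[i] + 1) / 2))
        if (n_ex > 1) {
          k <- 2L * (n_ex - 1L)
          bp <- sort(sample(seq(start, end - 1), k))
          seg_start <- c(start, bp + 1)
          seg_end <- c(bp, end)
          keep <- seq(1, 2 * n_ex - 1, by = 2)
          ex <- tibble(start = seg_start[keep], end = seg_end[keep])
        } else {
          ex <- tibble(start = start, end = end)
        }
        gid <<- gid + 1L
        tibble(
          gene_id = sprintf("g%04d", gid),
          chrom = names(chrom_lengths)[ci], strand = strand,
          start = start, end = end,
          tss = if (strand == "+") start else end,
          tes = if (strand == "+") end else start,
          exons = list(ex)
        )
      })
    })
    rows
  })
}

# Region instances (one row per contiguous class interval) from an
# index, including the intergenic complement.
.region_instances <- function(index) {
  gr <- index$regions
  tbl <- tibble(
    class = S4Vectors::mcols(gr)$class,
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr),
    end = GenomicRanges::end(gr),
    gene_id = S4Vectors::mcols(gr)$gene_id
  )
  inter <- purrr::map_dfr(names(index$chrom_lengths), function(ch) {
    sub <- gr[GenomicRanges::seqnames(gr) == ch]
    ir <- IRanges::reduce(IRanges::ranges(sub))
    gaps <- IRanges::gaps(ir, start = 1,
                          end = unname(index$chrom_lengths[ch]))
    if (length(gaps) == 0) return(NULL)
    tibble(class = "INTERGENIC", chrom = ch,
           start = IRanges::start(gaps), end = IRanges::end(gaps),
           gene_id = NA_character_)
  })
  bind_rows(tbl, inter) |> mutate(width = .data$end - .data$start + 1)
}

#' Simulate a dual-control ChIP peak experiment with planted truth
#'
#' Plants, for every requested region class, `counts_per_class` signal
#' peaks per contrast list (M1 = ChIP vs IgG, M2 = ChIP vs input).
#' A fraction `frac_common` of each class's peaks is shared — identical
#' intervals present in both lists — and the rest are list-specific;
#' every planted interval lies wholly inside one region instance of its
#' class, so the peak's midpoint class is its planted class by
#' construction. Signal folds are drawn from `fold_signal` (all above
#' the 2-fold cut-off), and `n_noise` additional sub-threshold peaks per
#' list are scattered anywhere with folds from `fold_noise`.
#'
#' @param genes Gene models (see [sim_gene_models()]).
#' @param chrom_lengths Named chromosome lengths.
#' @param counts_per_class Named integer vector over region classes,
#'   e.g. `c(UP2K = 5, EXON = 2)`.
#' @param fold_signal Signal fold range `c(lo, hi)`, `lo >= 2`.
#' @param fold_noise Noise fold range `c(lo, hi)`, `hi < 2`.
#' @param frac_common Fraction of each class's peaks shared between the
#'   two lists (0..1).
#' @param n_noise Noise peaks per list.
#' @param peak_width Peak width range in bp.
#' @param seed Integer seed.
#' @return List with `m1`, `m2` (peak tibbles: `peak_id`, `chrom`,
#'   `start`, `end`, `fold`), `truth` (one row per planted peak with
#'   class, membership, shared flag and folds) and the `region_index`
#'   used.
#' @export
sim_peak_experiment <- function(genes, chrom_lengths, counts_per_class,
                                fold_signal = c(2.5, 8),
                                fold_noise = c(0.2, 1.8),
                                frac_common = 1, n_noise = 0,
                                peak_width = c(150, 400), seed = 1) {
  stopifnot(fold_signal[1] >= 2, fold_noise[2] < 2,
            frac_common >= 0, frac_common <= 1,
            all(names(counts_per_class) %in% region_classes()))
  index <- region_map(genes, chrom_lengths)
  inst <- .region_instances(index)

  withr::with_seed(.derive_seed(seed, "peaks"), {
    planted <- purrr::imap_dfr(counts_per_class, function(k, cls) {
      if (k == 0) return(NULL)
      n_shared <- round(frac_common * k)
      n_total <- 2 * k - n_shared   # shared + m1-only + m2-only intervals
      avail <- filter(inst, .data$class == cls,
                      .data$width >= peak_width[1])
      if (nrow(avail) == 0) {
        abort(sprintf("No available area to place %s peaks.", cls))
      }
      if (nrow(avail) < n_total) {
        abort(sprintf(
          "Only %d %s region instances for %d requested peak intervals; simulate more genes.",
          nrow(avail), cls, n_total
        ))
      }
      picks <- avail[sample.int(nrow(avail), n_total), ]
      w <- pmin(sample(seq(peak_width[1], peak_width[2]),
                       n_total, replace = TRUE), picks$width)
      off <- floor(runif(n_total) * (picks$width - w + 1))
      start <- picks$start + off
      membership <- c(rep("both", n_shared), rep("m1", k - n_shared),
                      rep("m2", k - n_shared))
      tibble(
        class = cls, chrom = picks$chrom,
        start = start, end = start + w - 1,
        membership = membership
      )
    })
    planted <- planted |>
      mutate(
        peak_id = sprintf("pk%04d", row_number()),
        in_m1 = .data$membership %in% c("both", "m1"),
        in_m2 = .data$membership %in% c("both", "m2"),
        shared = .data$membership == "both",
        fold_m1 = if_else(.data$in_m1,
                          runif(n(), fold_signal[1], fold_signal[2]),
                          NA_real_),
        fold_m2 = if_else(.data$in_m2,
                          runif(n(), fold_signal[1], fold_signal[2]),
                          NA_real_),
        signal = TRUE
      )
    noise <- purrr::map_dfr(c("m1", "m2"), function(side) {
      if (n_noise == 0) return(NULL)
      ch <- sample(names(chrom_lengths), n_noise, replace = TRUE)
      w <- sample(seq(peak_width[1], peak_width[2]), n_noise, replace = TRUE)
      start <- floor(runif(n_noise) *
                       (unname(chrom_lengths[ch]) - w)) + 1
      tibble(
        class = NA_character_, chrom = ch, start = start, end = start + w - 1,
        membership = side,
        peak_id = sprintf("noise_%s_%03d", side, seq_len(n_noise)),
        in_m1 = side == "m1", in_m2 = side == "m2", shared = FALSE,
        fold_m1 = if (side == "m1")
          runif(n_noise, fold_noise[1], fold_noise[2]) else NA_real_,
        fold_m2 = if (side == "m2")
          runif(n_noise, fold_noise[1], fold_noise[2]) else NA_real_,
        signal = FALSE
      )
    })
    truth <- bind_rows(planted, noise) |> select(-"membership")
    pick_side <- function(truth, side_col, fold_col) {
      truth |>
        filter(.data[[side_col]]) |>
        select("peak_id", "chrom", "start", "end", fold = dplyr::all_of(fold_col))
    }
    list(
      m1 = pick_side(truth, "in_m1", "fold_m1"),
      m2 = pick_side(truth, "in_m2", "fold_m2"),
      truth = truth,
      index = index
    )
  })
}

#' Simulate a promoter-focused two-contrast peak study
#'
#' Generates a genome and a peak experiment whose filtered promoter
#' (Up2k) peak lists have prescribed sizes: `n_m1` peaks passing the
#' 2-fold cut against IgG, `n_m2` against input, and `n_common` shared
#' intervals, each planted in the Up2k region of a distinct gene. This
#' is a synthetic stand-in for a deposited peak-list table; defaults
#' reproduce the 212 / 162 / 57 structure.
#'
#' @param n_m1,n_m2 Peaks passing the filter in each contrast.
#' @param n_common Shared intervals (<= min(n_m1, n_m2)).
#' @param n_noise Sub-threshold peaks per list.
#' @param seed Integer seed.
#' @return As [sim_peak_experiment()], plus the generated `genes`.
#' @export
sim_chip_study <- function(n_m1 = 212, n_m2 = 162, n_common = 57,
                           n_noise = 40, seed = 1) {
  stopifnot(n_common <= min(n_m1, n_m2))
  n_genes <- n_m1 + n_m2 - n_common
  chrom_lengths <- setNames(rep(3e6, 21), paste0("chr", 1:21))
  need_chr <- ceiling(n_genes / 200) # capacity ~214 genes/chrom
  chrom_lengths <- chrom_lengths[seq_len(max(need_chr, 4))]
  genes <- sim_gene_models(n_genes, chrom_lengths,
                           gene_length = c(2000, 8000), seed = seed)
  index <- region_map(genes, chrom_lengths)
  inst <- filter(.region_instances(index), .data$class == "UP2K")

  withr::with_seed(.derive_seed(seed, "chip_study"), {
    picks <- inst[sample.int(nrow(inst), n_genes), ]
    w <- pmin(sample(150:400, n_genes, replace = TRUE), picks$width)
    off <- floor(runif(n_genes) * (picks$width - w + 1))
    membership <- c(rep("both", n_common),
                    rep("m1", n_m1 - n_common),
                    rep("m2", n_m2 - n_common))
    truth <- tibble(
      class = "UP2K", chrom = picks$chrom,
      start = picks$start + off, end = picks$start + off + w - 1,
      peak_id = sprintf("pk%04d", seq_len(n_genes)),
      in_m1 = membership %in% c("both", "m1"),
      in_m2 = membership %in% c("both", "m2"),
      shared = membership == "both",
      signal = TRUE
    ) |>
      mutate(
        fold_m1 = if_else(.data$in_m1, runif(n(), 2.5, 8), NA_real_),
        fold_m2 = if_else(.data$in_m2, runif(n(), 2.5, 8), NA_real_)
      )
    noise <- purrr::map_dfr(c("m1", "m2"), function(side) {
      if (n_noise == 0) return(NULL)
      ch <- sample(names(chrom_lengths), n_noise, replace = TRUE)
      w <- sample(150:400, n_noise, replace = TRUE)
      start <- floor(runif(n_noise) * (unname(chrom_lengths[ch]) - w)) + 1
      tibble(
        class = NA_character_, chrom = ch, start = start,
        end = start + w - 1,
        peak_id = sprintf("noise_%s_%03d", side, seq_len(n_noise)),
        in_m1 = side == "m1", in_m2 = side == "m2", shared = FALSE,
        signal = FALSE,
        fold_m1 = if (side == "m1") runif(n_noise, 0.2, 1.8) else NA_real_,
        fold_m2 = if (side == "m2") runif(n_noise, 0.2, 1.8) else NA_real_
      )
    })
    truth <- bind_rows(truth, noise)
    side_tbl <- function(side_col, fold_col) {
      truth |>
        filter(.data[[side_col]]) |>
        select("peak_id", "chrom", "start", "end",
               fold = dplyr::all_of(fold_col))
    }
    list(m1 = side_tbl("in_m1", "fold_m1"),
         m2 = side_tbl("in_m2", "fold_m2"),
         truth = truth, genes = genes, index = index)
  })
}

#' Simulate sequences with planted degenerate-motif occurrences
#'
#' Generates random DNA sequences and writes one concrete realization
#' of a motif (a random base from each position's allowed set) into
#' each of the first `n_planted` sequences, on a random strand (minus-
#' strand plants insert the reverse complement of the realization).
#' Random background can of course contain additional chance matches;
#' the truth records the planted occurrences.
#'
#' @param n_seqs Number of sequences.
#' @param seq_len Sequence length in bp.
#' @param patterns Patterns as in [scan_motif()].
#' @param n_planted Number of sequences receiving a planted occurrence
#'   (default all).
#' @param seed Integer seed.
#' @return List with `seqs` (tibble `seq_id`, `sequence`) and `truth`
#'   (tibble `seq_id`, `pattern_id`, `offset` 0-based, `strand`,
#'   `planted_span` — the forward-strand subsequence written).
#' @export
sim_motif_sequences <- function(n_seqs, seq_len = 500, patterns,
                                n_planted = n_seqs, seed = 1) {
  stopifnot(n_seqs >= 0, n_planted <= n_seqs, seq_len >= 1)
  patterns <- .as_pattern_list(patterns)
  withr::with_seed(.derive_seed(seed, "motif_seqs"), {
    seqs <- tibble(
      seq_id = sprintf("seq%03d", seq_len(n_seqs)),
      sequence = vapply(seq_len(n_seqs), function(i)
        paste(sample(c("A", "C", "G", "T"), seq_len, replace = TRUE),
              collapse = ""), character(1))
    )
    truth <- purrr::map_dfr(seq_len(n_planted), function(i) {
      pid <- sample(names(patterns), 1)
      pat <- patterns[[pid]]
      m <- pattern_length(pat)
      if (m > seq_len) abort("Pattern longer than sequence.")
      realization <- paste(vapply(pat$positions, function(p) {
        b <- strsplit(p, "", fixed = TRUE)[[1]]
        sample(b, 1)
      }, character(1)), collapse = "")
      strand <- sample(c("+", "-"), 1)
      span <- if (strand == "+") realization else .rc_string(realization)
      off <- sample.int(seq_len - m + 1, 1) - 1L
      s <- seqs$sequence[i]
      substr(s, off + 1, off + m) <- span
      seqs$sequence[i] <<- s
      tibble(seq_id = seqs$seq_id[i], pattern_id = pid,
             offset = off, strand = strand, planted_span = span)
    })
    list(seqs = seqs, truth = truth)
  })
}

.rc_string <- function(x) {
  comp <- c(A = "T", C = "G", G = "C", T = "A", N = "N")
  paste(rev(unname(comp[strsplit(toupper(x), "", fixed = TRUE)[[1]]])),
        collapse = "")
}

#' Simulate a lectin-microarray experiment with planted fold changes
#'
#' Generates spot-level data for a control and a treatment condition on
#' the same slide/block layout (default 3 slides x 3 blocks, so each
#' lectin contributes 9 block replicates). Treatment signal of lectin
#' *l* is the control signal scaled by `true_folds[l]` (1 when
#' unlisted). Spot noise is multiplicative Gaussian with coefficient of
#' variation `noise_cv` on the signal; backgrounds are additive
#' Gaussian around `bg_mean` with SD `bg_sd`, and every foreground
#' carries its own background draw on top of the signal, so at
#' `noise_cv = 0, bg_sd = 0` the downstream pipeline is exact.
#'
#' Because the protocol normalizes each block to the sum of lectin
#' medians, a planted raw fold `f` appears downstream as
#' `f * sum(s) / sum(f * s)` (`s` = base intensities); the truth table
#' records this `expected_nfi_fold` alongside the raw `true_fold`.
#'
#' @param true_folds Named numeric vector of planted treatment/control
#'   fold changes (> 0), e.g. `c("UEA-I" = 0.4, WFA = 2.5)`.
#' @param lectins Lectin identifiers; defaults to the shipped 37-lectin
#'   panel.
#' @param base_intensity Control signal level, recycled over lectins.
#' @param bg_mean,bg_sd Background level and SD (a.u., `bg_sd >= 0`).
#' @param n_slides,blocks_per_slide,spots_per_lectin Layout.
#' @param noise_cv Coefficient of variation of spot noise (>= 0).
#' @param seed Integer seed.
#' @return List with `spots` (tibble `condition`, `slide`, `block`,
#'   `lectin`, `foreground`, `background`) and `truth` (tibble
#'   `lectin`, `true_fold`, `expected_nfi_control`,
#'   `expected_nfi_treatment`, `expected_nfi_fold`).
#' @export
sim_lectin_dataset <- function(true_folds = c(), lectins = NULL,
                               base_intensity = 5000,
                               bg_mean = 100, bg_sd = 10,
                               n_slides = 3, blocks_per_slide = 3,
                               spots_per_lectin = 3, noise_cv = 0.05,
                               seed = 1) {
  if (noise_cv < 0) abort("noise_cv must be >= 0.")
  if (bg_sd < 0) abort("bg_sd must be >= 0.")
  if (any(true_folds <= 0)) abort("true_folds must be > 0.")
  if (is.null(lectins)) lectins <- lectin_panel()$lectin
  f <- setNames(rep(1, length(lectins)), lectins)
  if (length(true_folds)) {
    unknown <- setdiff(names(true_folds), lectins)
    if (length(unknown)) {
      abort(sprintf("true_folds for unknown lectin '%s'.", unknown[1]))
    }
    f[names(true_folds)] <- true_folds
  }
  s <- rep_len(base_intensity, length(lectins))
  truth <- tibble(
    lectin = lectins,
    true_fold = unname(f),
    expected_nfi_control = s / sum(s),
    expected_nfi_treatment = unname(f) * s / sum(unname(f) * s),
    expected_nfi_fold = unname(f) * sum(s) / sum(unname(f) * s)
  )
  layout <- tidyr::expand_grid(
    condition = c("control", "treatment"),
    slide = paste0("S", seq_len(n_slides)),
    block = paste0("B", seq_len(blocks_per_slide)),
    lectin = lectins,
    spot = seq_len(spots_per_lectin)
  )
  withr::with_seed(.derive_seed(seed, "lectin"), {
    base <- s[match(layout$lectin, lectins)]
    fold <- if_else(layout$condition == "treatment",
                    f[layout$lectin], 1)
    signal <- base * fold * (1 + noise_cv * rnorm(nrow(layout)))
    fg <- pmax(0, signal + bg_mean + bg_sd * rnorm(nrow(layout)))
    bg <- pmax(0, bg_mean + bg_sd * rnorm(nrow(layout)))
    spots <- layout |>
      mutate(foreground = fg, background = bg) |>
      select(-"spot")
    list(spots = spots, truth = truth)
  })
}

#' Simulate a qPCR Ct table with planted expression ratios
#'
#' Encodes each planted treatment/control expression ratio *r* as a
#' target-gene Ct shift of `-log2(r)` cycles relative to the reference
#' gene, plus Gaussian replicate noise of SD `noise_sd` cycles.
#'
#' @param true_ratios Named numeric vector of planted ratios (> 0),
#'   e.g. `c(FUT4 = 0.25)`.
#' @param reference Reference gene identifier (default `"ACTB"`).
#' @param ct_ref_base Reference-gene Ct level (cycles).
#' @param dct_base Baseline target-minus-reference dCt (cycles).
#' @param noise_sd Replicate noise SD in cycles (>= 0).
#' @param n_reps Replicates per gene and condition (>= 1).
#' @param seed Integer seed.
#' @return List with `ct` (tibble `condition`, `gene_id`, `role`,
#'   `replicate`, `ct`) and `truth` (tibble `gene_id`, `true_ratio`).
#' @export
sim_ct_dataset <- function(true_ratios, reference = "ACTB",
                           ct_ref_base = 20, dct_base = 5,
                           noise_sd = 0, n_reps = 3, seed = 1) {
  stopifnot(length(true_ratios) >= 1, !is.null(names(true_ratios)))
  if (any(true_ratios <= 0)) abort("true_ratios must be > 0.")
  if (noise_sd < 0) abort("noise_sd must be >= 0.")
  if (n_reps < 1) abort("n_reps must be >= 1.")
  genes <- names(true_ratios)
  withr::with_seed(.derive_seed(seed, "ct"), {
    grid <- tidyr::expand_grid(
      condition = c("control", "treatment"),
      gene_id = c(genes, reference),
      replicate = seq_len(n_reps)
    ) |>
      mutate(
        role = if_else(.data$gene_id == reference, "reference", "target"),
        shift = dplyr::case_when(
          .data$role == "reference" ~ -dct_base,
          .data$condition == "treatment" ~
            -log2(unname(true_ratios[.data$gene_id])),
          TRUE ~ 0
        ),
        ct = ct_ref_base + dct_base + .data$shift +
          noise_sd * rnorm(n())
      ) |>
      select("condition", "gene_id", "role", "replicate", "ct")
    list(ct = grid, truth = tibble(gene_id = genes,
                                   true_ratio = unname(true_ratios)))
  })
}
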