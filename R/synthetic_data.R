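## Synthetic data with known ground truth: genomes with planted
## inverted-repeat binding sites, fragment-smoothed ChIP/control coverage,
## SPR titration series and qPCR Ct tables. Every generator is
## bit-reproducible given (config, seed).

#' ChIP simulation configuration
#'
#' Parameters of the synthetic ChIP experiment. The defaults emulate the
#' study design this package targets at desk scale: a 1 Mb bacterial
#' replicon (stand-in for a ~6.7 Mb chromosome) with 40 genes, sonication
#' fragments of ~500 bp, a negative-binomial sequencing background of mean
#' 5 reads/base with size (dispersion) 3, and 10-fold enrichment at bound
#' sites.
#'
#' @param genome_length Replicon length in bp.
#' @param n_genes Number of genes to place.
#' @param fragment_length Sonication fragment size in bp; sets the
#'   half-width of the coverage pile-up around a bound site.
#' @param background_mean Mean per-base read coverage of the unenriched
#'   background.
#' @param background_dispersion Negative-binomial `size` parameter of the
#'   background (smaller = more overdispersed).
#' @param enrichment_fold Expected summit coverage at a planted site,
#'   as a multiple of `background_mean`; must be >= 1.
#' @param seed Integer seed; mandatory, all generators are deterministic
#'   under it.
#' @param circular Simulate a circular replicon?
#' @return A list of class `chip_sim_config`.
#' @export
chip_sim_config <- function(genome_length = 1e6, n_genes = 40,
                            fragment_length = 500, background_mean = 5,
                            background_dispersion = 3, enrichment_fold = 10,
                            seed, circular = TRUE) {
  stopifnot(fragment_length >= 1, enrichment_fold >= 1, background_mean > 0,
            background_dispersion > 0, genome_length >= 1, n_genes >= 0)
  if (missing(seed)) stop("chip_sim_config: seed is mandatory")
  structure(list(genome_length = as.integer(genome_length),
                 n_genes = as.integer(n_genes),
                 fragment_length = as.integer(fragment_length),
                 background_mean = background_mean,
                 background_dispersion = background_dispersion,
                 enrichment_fold = enrichment_fold,
                 seed = as.integer(seed),
                 circular = isTRUE(circular)),
            class = "chip_sim_config")
}

#' The eight-gene regulon target set used by the demonstration pipeline
#'
#' Gene names of the RccR regulon of *Pseudomonas fluorescens* SBW25 —
#' transhydrogenase (`pntAA`), PEP carboxykinase (`pckA`), pyruvate
#' dehydrogenase E1 (`aceE`), GAPDH (`gap`), a hypothetical protein
#' (`PFLU2154`), isocitrate lyase (`aceA`), malate synthase G (`glcB`) and
#' the autoregulated regulator itself (`rccR`). The synthetic genome names
#' eight of its genes after them so planted sites carry meaningful target
#' labels.
#'
#' @return Character vector of eight gene names.
#' @export
regulon_targets <- function() {
  c("pntAA", "pckA", "aceE", "gap", "PFLU2154", "aceA", "glcB", "rccR")
}

#' Default site plan for the demonstration pipeline
#'
#' One binding site upstream of each regulon target: the 28 bp class
#' (16 nt linker) everywhere except `pckA`, which carries the 29 bp
#' variant (17 nt linker), and `aceE`, which carries two copies of the
#' 15 bp class (3 nt linker) separated by 68 bp.
#'
#' @param targets Gene names to plant sites upstream of.
#' @return Data frame with columns `gene_id`, `site_class`,
#'   `arm_mismatches`.
#' @export
default_site_plan <- function(targets = regulon_targets()) {
  plan <- data.frame(gene_id = targets, site_class = "28bp",
                     arm_mismatches = 0L, stringsAsFactors = FALSE)
  plan$site_class[plan$gene_id == "pckA"] <- "29bp"
  if ("aceE" %in% targets) {
    plan <- plan[plan$gene_id != "aceE", ]
    plan <- rbind(plan,
                  data.frame(gene_id = c("aceE", "aceE"),
                             site_class = c("15bp", "15bp"),
                             arm_mismatches = c(0L, 0L)))
  }
  plan[order(match(plan$gene_id, targets)), , drop = FALSE]
}

#' Generate a synthetic bacterial replicon with annotation
#'
#' Background sequence is i.i.d. uniform over ACGT. Genes are
#' non-overlapping, placed one per equal-width slot with randomised
#' offsets, alternate strand, and keep intergenic spacers of at least
#' 400 bp so that binding sites can be planted upstream of any gene.
#'
#' @param config A [chip_sim_config()].
#' @param gene_ids Optional gene names (length `n_genes`); defaults to
#'   `g001, g002, ...`.
#' @param gene_length_range Range of gene lengths to draw from (bp).
#' @return A list with elements `genome` ([genome_record()]) and `genes`
#'   ([gene_features()] data frame).
#' @export
make_genome <- function(config, gene_ids = NULL,
                        gene_length_range = c(900L, 1500L)) {
  stopifnot(inherits(config, "chip_sim_config"))
  L <- config$genome_length
  n <- config$n_genes
  min_spacer <- 400L
  if (n > 0 &&
      n * (max(gene_length_range) + 2L * min_spacer) > L)
    stop("make_genome: cannot pack ", n, " genes into ", L, " bp with ",
         min_spacer, " bp spacers")
  set.seed(config$seed)
  seq <- paste(sample(c("A", "C", "G", "T"), L, replace = TRUE),
               collapse = "")
  if (n == 0L) {
    return(list(genome = genome_record("synthetic_1", seq, config$circular),
                genes = gene_features(character(), character(), integer(),
                                      integer(), character())))
  }
  if (is.null(gene_ids)) gene_ids <- sprintf("g%03d", seq_len(n))
  stopifnot(length(gene_ids) == n)
  slot <- L %/% n
  glen <- sample(seq(gene_length_range[1], gene_length_range[2]), n,
                 replace = TRUE)
  lo <- min_spacer
  hi <- slot - glen - min_spacer
  off <- lo + floor(stats::runif(n) * pmax(1L, hi - lo))
  start <- (seq_len(n) - 1L) * slot + off
  genes <- gene_features(gene_ids, "synthetic_1", start, start + glen,
                         ifelse(seq_len(n) %% 2L == 1L, "+", "-"))
  list(genome = genome_record("synthetic_1", seq, config$circular),
       genes = genes)
}

.site_linker_lengths <- c("15bp" = 3L, "28bp" = 16L, "29bp" = 17L)

## Compose one binding-site sequence: arm + random linker + arm, with
## `arm_mismatches` random substitutions confined to the arms.
.make_site_seq <- function(site_class, arm_mismatches = 0L,
                           left_arm = "TGTAGT", right_arm = "ACTACA") {
  L <- .site_linker_lengths[[site_class]]
  linker <- paste(sample(c("A", "C", "G", "T"), L, replace = TRUE),
                  collapse = "")
  site <- paste0(left_arm, linker, right_arm)
  if (arm_mismatches > 0L) {
    nl <- nchar(left_arm)
    arm_pos <- c(seq_len(nl), nchar(site) - nchar(right_arm) + seq_len(nchar(right_arm)))
    pos <- sample(arm_pos, arm_mismatches)
    for (p in pos) {
      old <- substr(site, p, p)
      substr(site, p, p) <- sample(setdiff(c("A", "C", "G", "T"), old), 1L)
    }
  }
  site
}

#' Plant pseudo-palindromic binding sites upstream of named genes
#'
#' Each planned site is written into the intergenic region upstream of its
#' target gene (strand-aware: before the start of a `+` gene, after the
#' end of a `-` gene). Sites are built as `TGTAGT` + random linker of
#' 3/16/17 nt + `ACTACA` for the 15/28/29 bp classes, with an optional
#' number of arm mismatches injected. When a gene receives several sites
#' they are stacked outwards with `pair_gap` bp between consecutive sites
#' (end of one to start of the next). The innermost site ends
#' `proximal_offset` bp from the gene boundary, so all sites of a plan of
#' up to two sites fall inside a 300 bp upstream window.
#'
#' @param genome A [genome_record()].
#' @param genes A [gene_features()] data frame.
#' @param site_plan Data frame with columns `gene_id`, `site_class`
#'   (`"15bp"`, `"28bp"` or `"29bp"`) and optionally `arm_mismatches`.
#' @param seed Integer seed for linker content and mismatch placement.
#' @param pair_gap Gap in bp between consecutive sites of one gene
#'   (default 68, the spacing of the two 15 bp sites the demonstration
#'   pipeline emulates).
#' @param proximal_offset Distance in bp from the gene boundary to the end
#'   of the innermost site.
#' @return A list with elements `genome` (sequence overwritten at the site
#'   positions) and `truth` (data frame of planted sites: `replicon_id`,
#'   `start`, `end`, `site_class`, `target_gene_id`, `sequence`).
#' @export
plant_sites <- function(genome, genes, site_plan, seed, pair_gap = 68L,
                        proximal_offset = 60L) {
  stopifnot(inherits(genome, "genome_record"))
  empty <- data.frame(replicon_id = character(), start = integer(),
                      end = integer(), site_class = character(),
                      target_gene_id = character(), sequence = character(),
                      stringsAsFactors = FALSE)
  if (is.null(site_plan) || nrow(site_plan) == 0L)
    return(list(genome = genome, truth = empty))
  if (is.null(site_plan$arm_mismatches)) site_plan$arm_mismatches <- 0L
  set.seed(seed)
  seq <- genome$sequence
  L <- nchar(seq)
  rows <- list()
  for (gid in unique(site_plan$gene_id)) {
    g <- genes[genes$gene_id == gid, , drop = FALSE]
    if (nrow(g) != 1L)
      stop("plant_sites: gene '", gid, "' not found (or ambiguous) in the ",
           "annotation")
    sub <- site_plan[site_plan$gene_id == gid, , drop = FALSE]
    dist <- proximal_offset   # gene boundary -> end of current site
    for (k in seq_len(nrow(sub))) {
      len <- .site_linker_lengths[[sub$site_class[k]]] + 12L
      if (g$strand == "+") {
        st <- g$start - dist - len
        en <- g$start - dist
      } else {
        st <- g$end + dist
        en <- g$end + dist + len
      }
      if (st < 0L || en > L)
        stop("plant_sites: no room upstream of gene '", gid, "'")
      hit_gene <- genes$start < en & genes$end > st
      if (any(hit_gene))
        stop("plant_sites: upstream region of gene '", gid,
             "' overlaps gene body of '",
             genes$gene_id[which(hit_gene)[1]], "'")
      site <- .make_site_seq(sub$site_class[k], sub$arm_mismatches[k])
      substr(seq, st + 1L, en) <- site
      rows[[length(rows) + 1L]] <-
        data.frame(replicon_id = genome$replicon_id, start = st, end = en,
                   site_class = sub$site_class[k], target_gene_id = gid,
                   sequence = site, stringsAsFactors = FALSE)
      dist <- dist + len + pair_gap
    }
  }
  truth <- do.call(rbind, rows)
  truth <- truth[order(truth$start), , drop = FALSE]
  rownames(truth) <- NULL
  g2 <- genome_record(genome$replicon_id, seq, genome$circular)
  list(genome = g2, truth = truth)
}

## Expected fragment pile-up around the planted sites: 1 across the site
## body, decaying linearly to 0 at fragment_length away (the coverage
## profile of uniformly positioned fragments overlapping a point source).
.site_kernel <- function(L, truth, fragment_length, circular) {
  k <- numeric(L)
  if (is.null(truth) || nrow(truth) == 0L) return(k)
  for (i in seq_len(nrow(truth))) {
    st <- truth$start[i]; en <- truth$end[i]   # 0-based half-open
    pos0 <- (st - fragment_length):(en + fragment_length - 1L)
    d <- ifelse(pos0 < st, st - pos0,
                ifelse(pos0 >= en, pos0 - en + 1L, 0L))
    w <- pmax(0, 1 - d / fragment_length)
    if (circular) {
      idx <- (pos0 %% L) + 1L
    } else {
      keep <- pos0 >= 0L & pos0 < L
      idx <- pos0[keep] + 1L
      w <- w[keep]
    }
    k[idx] <- pmax(k[idx], w)
  }
  k
}

#' Simulate ChIP and control coverage tracks
#'
#' The control track is per-base negative-binomial noise with the
#' configured background mean and dispersion. The ChIP track draws from
#' the same law with a position-dependent mean: background everywhere,
#' raised around each planted site by a triangular fragment pile-up kernel
#' scaled so the expected summit coverage equals
#' `enrichment_fold * background_mean`.
#'
#' @param genome A [genome_record()] (only its length and circularity are
#'   used).
#' @param truth_sites Planted-site data frame from [plant_sites()] (may be
#'   empty).
#' @param config A [chip_sim_config()].
#' @return A list with [coverage_track()] elements `chip` and `control`.
#' @export
simulate_chip_coverage <- function(genome, truth_sites, config) {
  stopifnot(inherits(config, "chip_sim_config"))
  L <- nchar(genome$sequence)
  kern <- .site_kernel(L, truth_sites, config$fragment_length,
                       genome$circular)
  mu_chip <- config$background_mean *
    (1 + (config$enrichment_fold - 1) * kern)
  set.seed(config$seed)
  chip <- stats::rnbinom(L, size = config$background_dispersion,
                         mu = mu_chip)
  control <- stats::rnbinom(L, size = config$background_dispersion,
                            mu = config$background_mean)
  list(chip = coverage_track(genome$replicon_id, chip, genome$circular),
       control = coverage_track(genome$replicon_id, control,
                                genome$circular))
}

#' The analyte concentration ladder used by the SPR titrations
#'
#' Ten two-fold dilutions from 100 uM down to 0.19 uM.
#'
#' @return Numeric vector of concentrations in uM, decreasing.
#' @export
spr_concentration_ladder <- function() {
  c(100, 50, 25, 12.5, 6.25, 3.125, 1.56, 0.78, 0.39, 0.19)
}

#' Simulate a steady-state SPR titration series
#'
#' Responses follow the one-site Langmuir isotherm
#' `R(C) = rmax * C / (kd + C)` plus i.i.d. Gaussian noise.
#'
#' @param kd True dissociation constant (uM), > 0.
#' @param rmax True saturation response (RU), > 0.
#' @param concentrations Analyte concentrations (uM).
#' @param noise_sd Gaussian noise standard deviation (RU).
#' @param seed Integer seed (required when `noise_sd > 0`).
#' @param dna_id,ru_ligand,mw_ligand,mw_analyte_monomer,stoichiometry,effector_concentration
#'   Passed through to [spr_series()]; the defaults describe a ~30 bp
#'   double-stranded capture oligo and a ~37 kDa analyte binding as a
#'   dimer.
#' @return An [spr_series()].
#' @export
simulate_spr_responses <- function(kd, rmax,
                                   concentrations = spr_concentration_ladder(),
                                   noise_sd = 0, seed = NULL,
                                   dna_id = "synthetic_site",
                                   ru_ligand = 50, mw_ligand = 19500,
                                   mw_analyte_monomer = 37000,
                                   stoichiometry = 1,
                                   effector_concentration = NA_real_) {
  stopifnot(kd > 0, rmax > 0)
  if (noise_sd > 0) {
    if (is.null(seed)) stop("simulate_spr_responses: seed required when ",
                            "noise_sd > 0")
    set.seed(seed)
  }
  resp <- rmax * concentrations / (kd + concentrations)
  if (noise_sd > 0) resp <- resp + stats::rnorm(length(resp), 0, noise_sd)
  spr_series(dna_id = dna_id, ru_ligand = ru_ligand, mw_ligand = mw_ligand,
             mw_analyte_monomer = mw_analyte_monomer,
             stoichiometry = stoichiometry,
             concentrations = concentrations, responses = resp,
             effector_concentration = effector_concentration)
}

#' Simulate a qPCR Ct table with known fold-changes
#'
#' Emits replicate Ct values for each target gene in a test sample and a
#' calibrator sample, plus the reference gene in both. The test-sample
#' target Ct is lowered by `log2(fold)` cycles relative to the calibrator
#' (the exact inverse of the 2^-ddCt readout); the reference gene is
#' constant across samples. Gaussian cycle noise is added to every well.
#'
#' @param true_folds Named numeric vector: true expression fold-change of
#'   each target gene in `sample_id` relative to `calibrator_id`.
#' @param ref_ct Reference-gene Ct (cycles).
#' @param noise_sd Per-well Gaussian Ct noise (cycles).
#' @param replicates Wells per gene-sample pair, >= 1 (3 emulates typical
#'   plate design).
#' @param seed Integer seed.
#' @param target_ct Calibrator-sample Ct of every target gene (cycles).
#' @param reference_gene,sample_id,calibrator_id Labels used in the table.
#' @return Data frame with columns `gene_id`, `sample_id`, `replicate`,
#'   `ct`.
#' @export
simulate_ct_table <- function(true_folds, ref_ct = 18, noise_sd = 0.1,
                              replicates = 3, seed, target_ct = 24,
                              reference_gene = "rpoD",
                              sample_id = "mutant",
                              calibrator_id = "WT") {
  stopifnot(replicates >= 1, !is.null(names(true_folds)),
            all(true_folds > 0))
  set.seed(seed)
  genes <- names(true_folds)
  grid <- expand.grid(gene_id = c(genes, reference_gene),
                      sample_id = c(sample_id, calibrator_id),
                      replicate = seq_len(replicates),
                      stringsAsFactors = FALSE)
  base <- ifelse(grid$gene_id == reference_gene, ref_ct, target_ct)
  shift <- ifelse(grid$gene_id != reference_gene &
                    grid$sample_id == sample_id,
                  -log2(true_folds[grid$gene_id]), 0)
  grid$ct <- base + shift +
    if (noise_sd > 0) stats::rnorm(nrow(grid), 0, noise_sd) else 0
  grid <- grid[order(grid$gene_id, grid$sample_id, grid$replicate), ]
  rownames(grid) <- NULL
  grid
}

#' Generate the full synthetic dataset in memory
#'
#' Genome + annotation, planted truth sites, ChIP and control coverage.
#'
#' @param config A [chip_sim_config()].
#' @param site_plan Site plan as for [plant_sites()]; the default plants
#'   the demonstration regulon ([default_site_plan()]) upstream of eight
#'   named genes spread over the replicon.
#' @param target_slots Which of the `n_genes` gene slots receive the
#'   target names (default: evenly spread).
#' @return List with `genome`, `genes`, `truth`, `chip`, `control`,
#'   `config`.
#' @export
generate_dataset <- function(config, site_plan = default_site_plan(),
                             target_slots = NULL) {
  targets <- unique(site_plan$gene_id)
  ids <- sprintf("g%03d", seq_len(config$n_genes))
  if (length(targets)) {
    if (is.null(target_slots))
      target_slots <- round(seq(2, config$n_genes - 1,
                                length.out = length(targets)))
    stopifnot(length(target_slots) == length(targets),
              !anyDuplicated(target_slots))
    ids[target_slots] <- targets
  }
  gen <- make_genome(config, gene_ids = ids)
  pl <- plant_sites(gen$genome, gen$genes, site_plan, seed = config$seed)
  cov <- simulate_chip_coverage(pl$genome, pl$truth, config)
  list(genome = pl$genome, genes = gen$genes, truth = pl$truth,
       chip = cov$chip, control = cov$control, config = config)
}

#' Write a synthetic dataset to an output directory
#'
#' Emits `genome.fasta`, `genes.gff3`, `truth_sites.bed` (+ TSV with
#' sequences), `chip.bedgraph`, `control.bedgraph` and a `config.txt`
#' provenance file (key = value, including the seed).
#'
#' @param dataset Result of [generate_dataset()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_synthetic_dataset <- function(dataset, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_genome_fasta(dataset$genome, file.path(dir, "genome.fasta"))
  write_gff3(dataset$genes, file.path(dir, "genes.gff3"))
  tr <- dataset$truth
  write_bed(data.frame(replicon_id = tr$replicon_id, start = tr$start,
                       end = tr$end,
                       name = paste0(tr$target_gene_id, "_", tr$site_class),
                       score = 0, strand = "+"),
            file.path(dir, "truth_sites.bed"))
  write_tsv(tr, file.path(dir, "truth_sites.tsv"))
  write_bedgraph(dataset$chip, file.path(dir, "chip.bedgraph"))
  write_bedgraph(dataset$control, file.path(dir, "control.bedgraph"))
  cfg <- dataset$config
  writeLines(paste0(names(cfg), " = ",
                    vapply(cfg, function(v) format(v, scientific = FALSE),
                           "")),
             file.path(dir, "config.txt"))
  invisible(dir)
}

#' The two 15 bp binding-site sequences of the aceE upstream region
#'
#' The pyruvate-dehydrogenase (`aceE`) promoter carries two slightly
#' different copies of the short site class, 68 bp apart; the first has
#' one mismatch in its right arm (terminal T instead of A).
#'
#' @return Character vector of the two 15-mers.
#' @export
aceE_sites <- function() c("TGTAGTTTTACTACT", "TGTAGTAAAACTACA")

#' Fixture regions carrying one binding site class per regulon target
#'
#' Builds one `region_length`-nt random-background region per target
#' gene. Every region receives an exact 28 bp site (16 nt linker) except
#' `aceE`, which instead receives the two 15 bp sites of [aceE_sites()]
#' separated by `pair_gap` bp -- the site architecture the demonstration
#' regulon emulates. Deterministic under `seed`.
#'
#' @param seed Integer seed.
#' @param region_length Region length in nt (>= 200).
#' @param targets Target names; `"aceE"` (if present) gets the 15 bp
#'   pair.
#' @param site_offset 0-based offset of the (first) site in each region.
#' @param pair_gap Gap between the two 15 bp sites, bp.
#' @return Named character vector of region sequences.
#' @export
make_site_regions <- function(seed, region_length = 300,
                              targets = regulon_targets(),
                              site_offset = 100, pair_gap = 68) {
  stopifnot(region_length >= site_offset + 15 + pair_gap + 15)
  set.seed(seed)
  out <- vapply(targets, function(tg) {
    region <- paste(sample(c("A", "C", "G", "T"), region_length,
                           replace = TRUE), collapse = "")
    if (tg == "aceE") {
      s <- aceE_sites()
      substr(region, site_offset + 1L, site_offset + 15L) <- s[1]
      st2 <- site_offset + 15L + pair_gap
      substr(region, st2 + 1L, st2 + 15L) <- s[2]
    } else {
      site <- .make_site_seq("28bp")
      substr(region, site_offset + 1L, site_offset + 28L) <- site
    }
    region
  }, "")
  names(out) <- targets
  out
}
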