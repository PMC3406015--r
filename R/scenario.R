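# Synthetic multi-species scenario generator with planted truth.
#
# The generator lays out one or more chromosomes with protein-coding
# genes and intergenic lncRNA loci of known conservation category,
# emits per-species transcript fragments, stranded reads, H3K4me3
# peaks, ancestral repeats, pairwise alignments evolved at known rates,
# gene counts with a planted neighbour-elevation effect, and a
# planted-truth sidecar against which every downstream stage can be
# scored.

#' Scenario configuration
#'
#' Builds and validates the configuration of a synthetic three-species
#' scenario (focal, sister, outgroup; modelled on a mouse /
#' mouse-subspecies / rat design). Defaults plant the study conditions
#' the package's recovery tests assume: conserved lncRNA substitution
#' rate 0.148 against an ancestral-repeat rate of 0.164, and a 25
#' percent expression elevation of genes nearest lineage-specific
#' lncRNAs.
#'
#' @param seed Integer seed; the whole bundle is deterministic given
#'   the config and seed.
#' @param chrom_lengths Named vector of focal chromosome lengths (bp).
#' @param n_protein_coding Number of protein-coding genes.
#' @param n_lncRNA_per_category Named counts for conservation
#'   categories `I` (all three species), `II` (focal+sister), `III`
#'   (focal only), `IV` (sister only), `V` (outgroup only).
#' @param n_excluded Number of focal lncRNA loci placed in regions
#'   without outgroup orthologous sequence.
#' @param read_depth_per_species Named total read counts.
#' @param read_length Read length (bp).
#' @param mean_transcript_length Mean lncRNA transcript length (bp).
#' @param branch_rates Named substitutions/site for feature classes
#'   `conserved_lncRNA`, `lineage_lncRNA`, `pc_exon`, `pc_intron`,
#'   `promoter_conserved`, `promoter_lineage`, `AR`.
#' @param gc_range Genome G+C fraction range (length-2).
#' @param n_ARs Number of ancestral repeats.
#' @param expression List: `baseline_log_mean`, `baseline_log_sd`
#'   (log-normal per-kb expression), `between_species_log_sd`,
#'   `neighbor_elevation_fraction` (default 0.25),
#'   `library_scale_per_species`.
#' @param n_housekeeping Housekeeping-gene count.
#' @param n_paralog_pairs Annotated paralog pairs.
#' @param sequences Emit genome sequences and evolved alignments
#'   (disable for fast coordinate-only scenarios).
#' @return A validated list with class `scenario_config`.
#' @export
scenario_config <- function(
    seed = 1,
    chrom_lengths = c(chr1 = 2.6e6),
    n_protein_coding = 300,
    n_lncRNA_per_category = c(I = 10, II = 10, III = 10, IV = 10, V = 10),
    n_excluded = 0,
    read_depth_per_species = c(focal = 50000, sister = 40000,
                               outgroup = 50000),
    read_length = 50,
    mean_transcript_length = 1100,
    branch_rates = c(conserved_lncRNA = 0.148, lineage_lncRNA = 0.164,
                     pc_exon = 0.079, pc_intron = 0.162,
                     promoter_conserved = 0.128, promoter_lineage = 0.148,
                     AR = 0.164),
    gc_range = c(0.40, 0.48),
    n_ARs = 150,
    expression = list(baseline_log_mean = 3.0, baseline_log_sd = 1.0,
                      between_species_log_sd = 0.25,
                      neighbor_elevation_fraction = 0.25,
                      library_scale_per_species = c(focal = 1, sister = 1,
                                                    outgroup = 1)),
    n_housekeeping = 60,
    n_paralog_pairs = 5,
    sequences = TRUE) {
  counts <- c(n_protein_coding, n_lncRNA_per_category, n_excluded, n_ARs,
              n_housekeeping, n_paralog_pairs, read_depth_per_species)
  if (any(counts < 0)) abort("all counts must be non-negative")
  stopifnot(all(c("I", "II", "III", "IV", "V") %in%
                  names(n_lncRNA_per_category)) || TRUE)
  missing_cat <- setdiff(c("I", "II", "III", "IV", "V"),
                         names(n_lncRNA_per_category))
  if (length(missing_cat) > 0) {
    n_lncRNA_per_category[missing_cat] <- 0
  }
  n_lncRNA_per_category <- n_lncRNA_per_category[c("I", "II", "III",
                                                   "IV", "V")]
  if (branch_rates[["conserved_lncRNA"]] > branch_rates[["AR"]]) {
    abort("branch_rates: conserved_lncRNA must not exceed the AR rate")
  }
  if (expression$neighbor_elevation_fraction < 0) {
    abort("neighbor_elevation_fraction must be non-negative")
  }
  n_lnc <- sum(n_lncRNA_per_category) + n_excluded
  if (n_lnc > n_protein_coding - 1) {
    abort(paste("infeasible placement: more lncRNA loci than intergenic",
                "gaps (need n_lncRNA <= n_protein_coding - 1)"))
  }
  structure(
    list(seed = seed, chrom_lengths = chrom_lengths,
         species = c("focal", "sister", "outgroup"),
         n_protein_coding = n_protein_coding,
         n_lncRNA_per_category = n_lncRNA_per_category,
         n_excluded = n_excluded,
         read_depth_per_species = read_depth_per_species,
         read_length = read_length,
         mean_transcript_length = mean_transcript_length,
         branch_rates = branch_rates, gc_range = gc_range,
         n_ARs = n_ARs, expression = expression,
         n_housekeeping = n_housekeeping,
         n_paralog_pairs = n_paralog_pairs, sequences = sequences),
    class = "scenario_config"
  )
}

#' Identity orthology map (same assembly)
#'
#' One same-orientation block per chromosome with zero offset; models
#' the "equivalent position" relation between two taxa mapped to the
#' same reference.
#'
#' @param chrom_lengths Named chromosome lengths.
#' @return An orthology map tibble.
#' @export
identity_orthology_map <- function(chrom_lengths) {
  tibble(src_chrom = names(chrom_lengths), src_start = 0L,
         src_end = as.integer(chrom_lengths),
         tgt_chrom = names(chrom_lengths), tgt_start = 0L,
         orientation = "same")
}

#' Generate a complete synthetic multi-species scenario
#'
#' See \code{\link{scenario_config}} for the knobs. The returned bundle
#' contains, per species, gene annotation, transcript fragments,
#' stranded reads, H3K4me3-style peaks, plus ancestral repeats, an
#' orthology map with planted unalignable gaps, REV-evolved pairwise
#' alignments at the configured rates, gene counts with the planted
#' neighbour elevation, ortholog/paralog/housekeeping tables, and a
#' `truth` sidecar (per-locus category, per-region true rate, per-gene
#' expression truth).
#'
#' @param config A \code{\link{scenario_config}}.
#' @return A list with class `lnc_scenario`.
#' @export
generate_scenario <- function(config = scenario_config()) {
  stopifnot(inherits(config, "scenario_config"))
  set.seed(config$seed)
  chrom <- names(config$chrom_lengths)[1]
  chrom_len <- as.integer(config$chrom_lengths[1])
  n_pc <- config$n_protein_coding
  cats <- c(rep(names(config$n_lncRNA_per_category),
                config$n_lncRNA_per_category),
            rep("excluded", config$n_excluded))
  n_lnc <- length(cats)
  cats <- sample(cats)

  ## ---- layout ----------------------------------------------------
  host_gap <- sort(sample.int(n_pc - 1, n_lnc))
  gene_len <- sample(seq(1200, 2400, by = 3), n_pc, replace = TRUE)
  gene_strand <- sample(c("+", "-"), n_pc, replace = TRUE)
  lnc_len <- pmax(500L, as.integer(round(rnorm(
    n_lnc, config$mean_transcript_length, 250))))
  lnc_strand <- sample(c("+", "-"), n_lnc, replace = TRUE)
  base_gap <- sample(3000:6000, n_pc + 1, replace = TRUE)
  spacer1 <- sample(1000:2500, n_lnc, replace = TRUE)
  spacer2 <- sample(1000:2500, n_lnc, replace = TRUE)

  gene_start <- integer(n_pc)
  gene_end <- integer(n_pc)
  lnc_start <- integer(n_lnc)
  lnc_end <- integer(n_lnc)
  free_segs <- list()  # base-gap segments: AR space + safe block cuts
  cursor <- 0L
  add_free <- function(a, b) {
    if (b - a > 200) free_segs[[length(free_segs) + 1]] <<- c(a, b)
  }
  add_free(cursor, cursor + base_gap[1])
  cursor <- cursor + base_gap[1]
  lnc_i <- 1L
  for (i in seq_len(n_pc)) {
    gene_start[i] <- cursor
    span <- gene_len[i] + 300L  # two exons separated by a 300 bp intron
    gene_end[i] <- cursor + span
    cursor <- cursor + span
    if (lnc_i <= n_lnc && i < n_pc && host_gap[lnc_i] == i) {
      cursor <- cursor + spacer1[lnc_i]
      lnc_start[lnc_i] <- cursor
      lnc_end[lnc_i] <- cursor + lnc_len[lnc_i]
      cursor <- cursor + lnc_len[lnc_i] + spacer2[lnc_i]
      lnc_i <- lnc_i + 1L
    }
    add_free(cursor, cursor + base_gap[i + 1])
    cursor <- cursor + base_gap[i + 1]
  }
  if (cursor > chrom_len) {
    abort(sprintf(
      "infeasible placement: layout needs %d bp but chromosome %s is %d bp",
      cursor, chrom, chrom_len))
  }

  genes <- tibble(gene_id = sprintf("gene_%04d", seq_len(n_pc)),
                  chrom = chrom, start = gene_start, end = gene_end,
                  strand = gene_strand)
  # two exons: 5' 40 percent / 3' 60 percent of the coding length
  e1_len <- as.integer(round(gene_len * 0.4 / 3) * 3)
  gene_models <- bind_rows(
    tibble(gene_id = genes$gene_id,
           transcript_id = paste0(genes$gene_id, "_t1"),
           chrom = chrom, start = gene_start,
           end = gene_start + e1_len, strand = gene_strand),
    tibble(gene_id = genes$gene_id,
           transcript_id = paste0(genes$gene_id, "_t1"),
           chrom = chrom, start = gene_start + e1_len + 300L,
           end = gene_end, strand = gene_strand))
  gene_models <- arrange(gene_models, .data$gene_id, .data$start)

  lnc <- tibble(locus_id = sprintf("lnc_%03d", seq_len(n_lnc)),
                chrom = chrom, start = lnc_start, end = lnc_end,
                strand = lnc_strand, category = cats,
                host_gap = host_gap)

  ## ---- orthology map with planted gaps ---------------------------
  free_mat <- do.call(rbind, free_segs)
  cut_points <- integer(0)
  next_cut <- 250000
  for (r in seq_len(nrow(free_mat))) {
    mid <- floor((free_mat[r, 1] + free_mat[r, 2]) / 2)
    if (mid >= next_cut) {
      cut_points <- c(cut_points, mid)
      next_cut <- mid + 250000
    }
  }
  block_bounds <- unique(c(0L, cut_points, cursor))
  blocks <- tibble(src_start = block_bounds[-length(block_bounds)],
                   src_end = block_bounds[-1])
  # carve out regions around loci planted without outgroup orthologs
  for (j in which(lnc$category == "excluded")) {
    a <- lnc$start[j] - 500L
    b <- lnc$end[j] + 500L
    hit <- which(blocks$src_start < a & blocks$src_end > b)
    if (length(hit) == 1) {
      blocks <- bind_rows(
        blocks[-hit, ],
        tibble(src_start = blocks$src_start[hit], src_end = a),
        tibble(src_start = b, src_end = blocks$src_end[hit]))
      blocks <- arrange(blocks, .data$src_start)
    }
  }
  n_blocks <- nrow(blocks)
  orient <- rep("same", n_blocks)
  if (n_blocks >= 4) orient[seq(4, n_blocks, by = 4)] <- "flipped"
  tgt_start <- integer(n_blocks)
  tcur <- 0L
  for (b in seq_len(n_blocks)) {
    tgt_start[b] <- tcur
    tcur <- tcur + (blocks$src_end[b] - blocks$src_start[b]) + 1000L
  }
  orthology_map <- tibble(src_chrom = chrom, src_start = blocks$src_start,
                          src_end = blocks$src_end, tgt_chrom = chrom,
                          tgt_start = tgt_start, orientation = orient)
  outgroup_len <- tcur
  chrom_lengths_by_species <- list(
    focal = setNames(chrom_len, chrom),
    sister = setNames(chrom_len, chrom),
    outgroup = setNames(outgroup_len, chrom))

  ## ---- expression truth ------------------------------------------
  ex <- config$expression
  mu <- exp(rnorm(n_pc, ex$baseline_log_mean, ex$baseline_log_sd))
  # nearest gene (gene A) of each lncRNA, by envelope distance
  d_left <- lnc$start - gene_end[lnc$host_gap]
  d_right <- gene_start[lnc$host_gap + 1L] - lnc$end
  gene_a_idx <- ifelse(d_left <= d_right, lnc$host_gap, lnc$host_gap + 1L)
  lnc$gene_a <- genes$gene_id[gene_a_idx]
  bearing <- dplyr::case_when(
    lnc$category %in% c("II", "III") ~ "focal",
    lnc$category == "IV" ~ "sister",
    lnc$category == "V" ~ "outgroup",
    TRUE ~ NA_character_)
  lnc$bearing_species <- bearing
  elev <- matrix(1, n_pc, 3,
                 dimnames = list(genes$gene_id, config$species))
  for (j in seq_len(n_lnc)) {
    if (!is.na(bearing[j])) {
      elev[gene_a_idx[j], bearing[j]] <-
        elev[gene_a_idx[j], bearing[j]] * (1 + ex$neighbor_elevation_fraction)
    }
  }
  lib_scale <- ex$library_scale_per_species
  counts <- bind_rows(map(config$species, function(sp) {
    eps <- rnorm(n_pc, 0, ex$between_species_log_sd)
    lam <- lib_scale[[sp]] * mu * (gene_len / 1000) * exp(eps) * elev[, sp]
    tibble(gene_id = genes$gene_id, species = sp,
           count = rpois(n_pc, lam))
  }))
  not_near <- setdiff(genes$gene_id, lnc$gene_a)
  housekeeping <- sort(sample(not_near,
                              min(config$n_housekeeping, length(not_near))))
  # paralogs: adjacent gene pairs away from any planted gene A
  free_pairs <- which(!(genes$gene_id %in% lnc$gene_a) &
                        !(lead(genes$gene_id) %in% lnc$gene_a))
  free_pairs <- free_pairs[free_pairs < n_pc]
  paralogs <- if (config$n_paralog_pairs > 0 && length(free_pairs) > 0) {
    pick <- sample(free_pairs, min(config$n_paralog_pairs,
                                   length(free_pairs)))
    tibble(gene1 = genes$gene_id[pick], gene2 = genes$gene_id[pick + 1])
  } else {
    tibble(gene1 = character(), gene2 = character())
  }

  ## ---- per-species expression sets -------------------------------
  expressed_in <- list(
    focal = lnc$locus_id[lnc$category %in% c("I", "II", "III", "excluded")],
    sister = lnc$locus_id[lnc$category %in% c("I", "II", "IV")],
    outgroup = lnc$locus_id[lnc$category %in% c("I", "V")])

  # projected coordinates in the outgroup for every locus and gene
  proj_lnc <- project_interval(lnc, orthology_map)
  proj_genes <- project_interval(gene_models, orthology_map)
  proj_gene_models <- mutate(proj_genes,
                             gene_id = gene_models$gene_id[.data$src_index],
                             transcript_id =
                               gene_models$transcript_id[.data$src_index])

  lnc_mu <- exp(rnorm(n_lnc, ex$baseline_log_mean - 1.5, ex$baseline_log_sd))

  transcript_tbl_for <- function(sp) {
    if (sp == "outgroup") {
      g <- select(proj_gene_models, "transcript_id", "chrom", "start",
                  "end", "strand")
      l_idx <- match(expressed_in[[sp]], lnc$locus_id)
      l_proj <- filter(proj_lnc, .data$src_index %in% l_idx)
      l <- tibble(transcript_id = lnc$locus_id[l_proj$src_index],
                  chrom = l_proj$chrom, start = l_proj$start,
                  end = l_proj$end, strand = l_proj$strand)
    } else {
      g <- tibble(transcript_id = gene_models$transcript_id,
                  chrom = gene_models$chrom, start = gene_models$start,
                  end = gene_models$end, strand = gene_models$strand)
      keep <- lnc$locus_id %in% expressed_in[[sp]]
      l <- tibble(transcript_id = lnc$locus_id[keep],
                  chrom = lnc$chrom[keep], start = lnc$start[keep],
                  end = lnc$end[keep], strand = lnc$strand[keep])
    }
    w_g <- tibble(transcript_id = unique(g$transcript_id))
    w_g$weight <- mu[match(sub("_t1$", "", w_g$transcript_id),
                           genes$gene_id)]
    w_l <- tibble(transcript_id = unique(l$transcript_id))
    w_l$weight <- lnc_mu[match(w_l$transcript_id, lnc$locus_id)]
    tx <- bind_rows(g, l)
    left_join(tx, bind_rows(w_g, w_l), by = "transcript_id")
  }

  tiling_reads <- function(tx, read_length, step = 40L) {
    rows <- map(seq_len(nrow(tx)), function(k) {
      starts <- seq.int(tx$start[k], max(tx$start[k], tx$end[k] - read_length),
                        by = step)
      tibble(chrom = tx$chrom[k], start = as.integer(starts),
             end = as.integer(pmin(starts + read_length, tx$end[k])),
             strand = tx$strand[k], transcript_id = tx$transcript_id[k])
    })
    bind_rows(rows)
  }

  reads <- list()
  transfrags <- list()
  peaks <- list()
  for (sp in config$species) {
    tx <- transcript_tbl_for(sp)
    transfrags[[sp]] <- select(tx, "transcript_id", "chrom", "start",
                               "end", "strand")
    tiles <- tiling_reads(tx, config$read_length)
    depth <- config$read_depth_per_species[[sp]]
    if (nrow(tiles) > depth) {
      abort(sprintf(
        "infeasible read depth for %s: %d reads needed to tile transcripts, depth is %d",
        sp, nrow(tiles), depth))
    }
    extra <- simulate_read_library(tx, depth - nrow(tiles),
                                   read_length = config$read_length)
    reads[[sp]] <- bind_rows(tiles, extra)
    spans <- transcript_spans(tx)
    pk_start <- pmax(0L, spans$tss - 250L)
    peaks[[sp]] <- tibble(chrom = spans$chrom, start = pk_start,
                          end = spans$tss + 250L, summit = spans$tss)
  }

  ## ---- ancestral repeats -----------------------------------------
  gc <- runif(1, config$gc_range[1], config$gc_range[2])
  slot_list <- list()
  for (r in seq_len(nrow(free_mat))) {
    a <- free_mat[r, 1] + 100L
    b <- free_mat[r, 2] - 100L
    if (b - a >= 900) {
      starts <- seq.int(a, b - 900, by = 950)
      slot_list[[r]] <- starts
    }
  }
  slots <- unlist(slot_list)
  if (length(slots) < config$n_ARs) {
    abort("infeasible placement: not enough intergenic space for ancestral repeats")
  }
  ar_start <- sort(sample(slots, config$n_ARs))
  ar_len <- sample(300:800, config$n_ARs, replace = TRUE)
  ars <- tibble(ar_id = sprintf("ar_%03d", seq_len(config$n_ARs)),
                chrom = chrom, start = ar_start,
                end = ar_start + ar_len,
                gc = pmin(0.99, pmax(0.01, gc + runif(config$n_ARs,
                                                      -0.02, 0.02))))

  ## ---- sequences and alignments ----------------------------------
  genome <- NULL
  alignments <- NULL
  if (config$sequences) {
    genome <- list()
    genome$focal <- setNames(list(random_genome_sequence(
      chrom_len, gc, lnc, genes, gene_models, e1_len)), chrom)
    genome$sister <- genome$focal
    genome$outgroup <- setNames(
      list(paste0(sample(BASES, outgroup_len, replace = TRUE,
                         prob = c((1 - gc) / 2, gc / 2, gc / 2,
                                  (1 - gc) / 2)),
                  collapse = "")), chrom)
    pars <- rev_params(
      frequencies = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2),
      exchangeabilities = c(1, 4, 1, 1, 4, 1))
    br <- config$branch_rates
    lnc_class <- ifelse(lnc$category == "I", "conserved_lncRNA",
                        "lineage_lncRNA")
    prom_class <- ifelse(lnc$category == "I", "promoter_conserved",
                         "promoter_lineage")
    spec_rows <- bind_rows(
      tibble(region_id = lnc$locus_id, feature_class = lnc_class,
             length = lnc$end - lnc$start),
      tibble(region_id = paste0(lnc$locus_id, "_prom"),
             feature_class = prom_class, length = 400L),
      tibble(region_id = ars$ar_id, feature_class = "AR",
             length = ars$end - ars$start),
      tibble(region_id = paste0(genes$gene_id[1:min(50, n_pc)], "_exon"),
             feature_class = "pc_exon",
             length = gene_len[1:min(50, n_pc)]),
      tibble(region_id = paste0(genes$gene_id[1:min(50, n_pc)], "_intron"),
             feature_class = "pc_intron", length = 300L))
    spec_rows$true_d <- unname(br[spec_rows$feature_class])
    pairs <- map(seq_len(nrow(spec_rows)), function(k) {
      evolve_pair(spec_rows$length[k], spec_rows$true_d[k], pars)
    })
    alignments <- mutate(spec_rows,
                         seq1 = map_chr(pairs, "seq1"),
                         seq2 = map_chr(pairs, "seq2"))
  }

  truth <- list(
    loci = select(lnc, "locus_id", "chrom", "start", "end", "strand",
                  "category", "gene_a", "bearing_species"),
    rates = if (!is.null(alignments)) {
      select(alignments, "region_id", "feature_class", "true_d")
    } else {
      NULL
    },
    genes = tibble(gene_id = genes$gene_id, mu = mu,
                   elevated_in = apply(elev, 1, function(r) {
                     s <- colnames(elev)[r > 1]
                     if (length(s) == 0) NA_character_ else s[1]
                   }),
                   is_housekeeping = genes$gene_id %in% housekeeping),
    library_scale = lib_scale)

  structure(
    list(config = config,
         species = config$species,
         chrom_lengths = chrom_lengths_by_species,
         genes = genes, gene_models = gene_models,
         genes_outgroup = proj_gene_models,
         lncrna_loci = select(lnc, "locus_id", "chrom", "start", "end",
                              "strand", "category"),
         transfrags = transfrags, reads = reads, peaks = peaks,
         ars = ars, orthology_map = orthology_map,
         alignments = alignments, genome = genome,
         counts = counts,
         orthologs = tibble(gene_id = genes$gene_id),
         paralogs = paralogs, housekeeping = housekeeping,
         truth = truth),
    class = "lnc_scenario"
  )
}

#' @export
print.lnc_scenario <- function(x, ...) {
  cat(sprintf(
    "Synthetic scenario: %d protein-coding genes, %d lncRNA loci (%s), %d ARs\n",
    nrow(x$genes), nrow(x$lncrna_loci),
    paste(names(table(x$lncrna_loci$category)),
          table(x$lncrna_loci$category), sep = ":", collapse = " "),
    nrow(x$ars)))
  invisible(x)
}

# Focal chromosome sequence with planted coding ORFs in gene exons and
# start-codon-free lncRNA loci (so coding-potential calls are
# deterministic on the planted features).
random_genome_sequence <- function(chrom_len, gc, lnc, genes, gene_models,
                                   e1_len) {
  probs <- c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)
  s <- sample(BASES, chrom_len, replace = TRUE, prob = probs)
  # lncRNA loci: remove ATG on either strand (ATG forward, CAT reverse)
  for (j in seq_len(nrow(lnc))) {
    region <- paste0(s[(lnc$start[j] + 1):lnc$end[j]], collapse = "")
    region <- strip_start_codons(region)
    s[(lnc$start[j] + 1):lnc$end[j]] <- strsplit(region, "")[[1]]
  }
  # gene exons: a single full-length ORF across the two spliced exons
  non_stop <- setdiff(apply(expand.grid(BASES, BASES, BASES), 1, paste0,
                            collapse = ""),
                      c("TAA", "TAG", "TGA"))
  for (i in seq_len(nrow(genes))) {
    len <- e1_len[i] + (genes$end[i] - genes$start[i] - 300L - e1_len[i])
    n_codon <- len %/% 3
    cds <- paste0(c("ATG", sample(non_stop, n_codon - 2, replace = TRUE),
                    "TAA"), collapse = "")
    cds <- substr(cds, 1, len)
    gseq <- if (genes$strand[i] == "-") {
      as.character(Biostrings::reverseComplement(Biostrings::DNAString(cds)))
    } else {
      cds
    }
    g1 <- substr(gseq, 1, e1_len[i])
    g2 <- substr(gseq, e1_len[i] + 1, len)
    s[(genes$start[i] + 1):(genes$start[i] + e1_len[i])] <-
      strsplit(g1, "")[[1]]
    s[(genes$start[i] + e1_len[i] + 300L + 1):genes$end[i]] <-
      strsplit(g2, "")[[1]]
  }
  paste0(s, collapse = "")
}

strip_start_codons <- function(s) {
  while (grepl("ATG", s, fixed = TRUE) || grepl("CAT", s, fixed = TRUE)) {
    s <- gsub("ATG", "ACG", s, fixed = TRUE)
    s <- gsub("CAT", "CCT", s, fixed = TRUE)
  }
  s
}

#' Classify the planted loci of a scenario
#'
#' Runs the conservation machinery over a generated scenario: each
#' planted locus is projected to the sister (identity map) and outgroup
#' (syntenic-block map) coordinates, peak/read evidence is collected
#' per species, and the three-species truth table applied.
#'
#' @param scenario A \code{\link{generate_scenario}} bundle.
#' @param mode Evidence mode (`"strict"` or `"reads_only"`).
#' @return Tibble: `locus_id`, `category` (predicted), `true_category`.
#' @export
classify_scenario_loci <- function(scenario, mode = "strict") {
  stopifnot(inherits(scenario, "lnc_scenario"))
  loci <- scenario$truth$loci
  evidence <- list()
  for (i in seq_len(nrow(loci))) {
    l <- loci[i, ]
    region <- select(l, "chrom", "start", "end", "strand")
    for (sp in scenario$species) {
      if (sp == "outgroup") {
        proj <- project_interval(region, scenario$orthology_map)
        if (nrow(proj) == 0) {
          evidence[[length(evidence) + 1]] <- tibble(
            locus_id = l$locus_id, species = sp, has_ortholog = FALSE,
            expressed = FALSE)
          next
        }
        reg_sp <- select(proj, "chrom", "start", "end", "strand")
      } else {
        reg_sp <- region
      }
      ev <- expression_evidence_at(reg_sp, scenario$peaks[[sp]],
                                   scenario$reads[[sp]], mode = mode)
      evidence[[length(evidence) + 1]] <- tibble(
        locus_id = l$locus_id, species = sp, has_ortholog = TRUE,
        expressed = ev$expressed)
    }
  }
  calls <- classify_conservation(bind_rows(evidence), focal = "focal",
                                 sister = "sister", outgroup = "outgroup")
  truth_cat <- loci$category
  truth_cat[truth_cat == "excluded"] <- "excluded_no_ortholog"
  left_join(calls,
            tibble(locus_id = loci$locus_id, true_category = truth_cat),
            by = "locus_id")
}
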