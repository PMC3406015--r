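# Light-weight generators for expression-comparison and
# overlap-enrichment studies. These skip genome sequence and read
# placement entirely so that many replicate studies can be simulated
# cheaply for power and calibration checks.

#' Simulate a two-species expression comparison study
#'
#' Draws per-kb expression levels log-normally for a panel of
#' one-to-one orthologous genes, assigns disjoint gene groups (genes A
#' near lineage-specific lncRNAs, genes A near conserved lncRNAs,
#' genes B, housekeeping genes, background), plants an expression
#' elevation of `(1 + elevation)` in species X for the lineage-A group
#' only, optionally perturbs a fraction of background genes
#' symmetrically (for normalization stress tests), scales species Y's
#' library by `scale_y`, and emits Poisson counts.
#'
#' @param n_genes Total ortholog panel size.
#' @param n_lineage_a,n_conserved_a,n_b,n_housekeeping Group sizes.
#' @param elevation Planted fractional elevation for lineage genes A
#'   (default 0.25).
#' @param scale_y Library scaling of species Y (default 1).
#' @param perturbed_fraction Fraction of background genes given a
#'   symmetric two-fold perturbation (half up in X, half up in Y).
#' @param baseline_log_mean,baseline_log_sd Log-normal expression
#'   parameters (per-kb rate).
#' @param between_species_log_sd Between-species biological noise (log
#'   scale).
#' @param seed Integer seed.
#' @return List with class `expression_study`: `records` tibble
#'   (`gene_id`, `group`, `count_x`, `count_y`, `length_x`,
#'   `length_y`, `bearing`), `truth` (planted elevation, scaling).
#' @export
simulate_expression_study <- function(n_genes = 2000, n_lineage_a = 137,
                                      n_conserved_a = 148, n_b = 120,
                                      n_housekeeping = 230,
                                      elevation = 0.25, scale_y = 1,
                                      perturbed_fraction = 0,
                                      baseline_log_mean = 3,
                                      baseline_log_sd = 1,
                                      between_species_log_sd = 0.25,
                                      seed = NULL) {
  n_special <- n_lineage_a + n_conserved_a + n_b + n_housekeeping
  if (n_special > n_genes) {
    abort("group sizes exceed the gene panel size")
  }
  if (!is.null(seed)) set.seed(seed)
  gene_id <- sprintf("gene_%05d", seq_len(n_genes))
  group <- rep("background", n_genes)
  idx <- sample.int(n_genes, n_special)
  group[idx] <- rep(c("lineage_A", "conserved_A", "gene_B", "housekeeping"),
                    c(n_lineage_a, n_conserved_a, n_b, n_housekeeping))
  len <- sample(500:3000, n_genes, replace = TRUE)
  mu <- exp(rnorm(n_genes, baseline_log_mean, baseline_log_sd))
  eps_x <- rnorm(n_genes, 0, between_species_log_sd)
  eps_y <- rnorm(n_genes, 0, between_species_log_sd)
  elev_x <- ifelse(group == "lineage_A", 1 + elevation, 1)
  pert_x <- rep(1, n_genes)
  pert_y <- rep(1, n_genes)
  if (perturbed_fraction > 0) {
    bg <- which(group == "background")
    n_pert <- round(perturbed_fraction * n_genes)
    if (n_pert > length(bg)) {
      abort("perturbed_fraction exceeds the available background genes")
    }
    pert_idx <- sample(bg, n_pert)
    up_x <- pert_idx[seq_len(floor(n_pert / 2))]
    up_y <- setdiff(pert_idx, up_x)
    pert_x[up_x] <- 2
    pert_y[up_y] <- 2
  }
  lam_x <- mu * (len / 1000) * exp(eps_x) * elev_x * pert_x
  lam_y <- scale_y * mu * (len / 1000) * exp(eps_y) * pert_y
  records <- tibble(
    gene_id = gene_id, group = group,
    count_x = rpois(n_genes, lam_x),
    count_y = rpois(n_genes, lam_y),
    length_x = len, length_y = len,
    bearing = ifelse(group == "lineage_A", "x", NA_character_))
  structure(
    list(records = records,
         truth = list(elevation = elevation, scale_y = scale_y,
                      perturbed_fraction = perturbed_fraction)),
    class = "expression_study"
  )
}

#' Run the full expression comparison on a simulated study
#'
#' TMM normalization on the whole ortholog panel, FPKM, oriented ln
#' fold-differences (lncRNA-bearing species as numerator for the
#' lineage genes A; random orientation for every baseline group) and
#' Mann-Whitney shift tests of every group against the housekeeping
#' baseline.
#'
#' @param study A \code{\link{simulate_expression_study}} result.
#' @param assumed_fraction TMM similar-expression fraction.
#' @param seed Seed for the random baseline orientation.
#' @return List: `factors` (\code{\link{tmm_factors}}), `folds`
#'   (per-gene tibble with `group` and `value`), `tests`
#'   (\code{\link{expression_shift_test}} output).
#' @export
analyze_expression_study <- function(study, assumed_fraction = 0.6,
                                     seed = NULL) {
  stopifnot(inherits(study, "expression_study"))
  rec <- study$records
  factors <- tmm_factors(rec$count_x, rec$count_y,
                         assumed_fraction = assumed_fraction)
  fpkm <- fpkm_table(rec, factors)
  oriented <- filter(fpkm, .data$group == "lineage_A")
  baseline_grp <- filter(fpkm, .data$group != "lineage_A")
  f_bear <- if (nrow(oriented) > 0) {
    fold_differences(oriented, orientation = "bearing")
  } else {
    tibble(gene_id = character(), value = numeric(),
           orientation = character())
  }
  f_rand <- fold_differences(baseline_grp, orientation = "random_xy",
                             seed = seed)
  folds <- bind_rows(
    left_join(f_bear, select(rec, "gene_id", "group"), by = "gene_id"),
    left_join(f_rand, select(rec, "gene_id", "group"), by = "gene_id"))
  baseline <- folds$value[folds$group == "housekeeping"]
  tests <- expression_shift_test(
    select(filter(folds, .data$group != "housekeeping"),
           "group", "value"),
    baseline)
  list(factors = factors, folds = folds, tests = tests,
       housekeeping_median = median(baseline))
}

#' Simulate a planted territory-enrichment scenario
#'
#' Builds a tiled workspace, marks a fraction of it as annotation
#' (e.g. liver-expressed gene territories), and places segments
#' (lncRNA loci) so that the fraction landing inside the annotation is
#' `fold` times the annotation's share of the workspace.
#'
#' @param n_windows Number of workspace windows.
#' @param window_bp Window width.
#' @param annotation_fraction Fraction of windows annotated.
#' @param fold Planted enrichment fold (`fold * annotation_fraction`
#'   must be at most 1).
#' @param n_segments Number of segments.
#' @param segment_bp Segment width.
#' @param seed Integer seed.
#' @return List: `segments`, `annotation`, `workspace` tibbles and the
#'   planted `fold`.
#' @export
simulate_enrichment_scenario <- function(n_windows = 300, window_bp = 10000,
                                         annotation_fraction = 0.4,
                                         fold = 1.6, n_segments = 150,
                                         segment_bp = 500, seed = NULL) {
  q <- fold * annotation_fraction
  if (q > 1) abort("fold * annotation_fraction must be at most 1")
  if (!is.null(seed)) set.seed(seed)
  starts <- (seq_len(n_windows) - 1L) * (window_bp + 1000L)
  workspace <- tibble(chrom = "chr1", start = starts,
                      end = starts + window_bp)
  ann_idx <- sort(sample.int(n_windows, round(annotation_fraction *
                                                n_windows)))
  annotation <- workspace[ann_idx, ]
  n_in <- round(q * n_segments)
  pick_in <- sample(ann_idx, n_in, replace = TRUE)
  pick_out <- sample(setdiff(seq_len(n_windows), ann_idx),
                     n_segments - n_in, replace = TRUE)
  win <- c(pick_in, pick_out)
  seg_start <- workspace$start[win] +
    floor(runif(n_segments) * (window_bp - segment_bp))
  segments <- tibble(chrom = "chr1", start = as.integer(seg_start),
                     end = as.integer(seg_start + segment_bp))
  list(segments = segments, annotation = annotation,
       workspace = workspace, fold = fold)
}
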