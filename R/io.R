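# Readers and writers for the standard interchange formats: BED6
# (reads, segments), BED with score (ancestral repeats + G+C),
# narrowPeak (H3K4me3 enriched regions), GFF3 (gene models, 1-based
# inclusive, converted at this boundary), FASTA (genomes), paired
# FASTA (pairwise alignments), TSV (counts, orthology map) and JSON
# (planted-truth sidecar).

#' Write a BED6 file
#'
#' @param x Interval tibble (`chrom`, `start`, `end`, optional `name`,
#'   `score`, `strand`).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(x, path) {
  x <- validate_intervals(as_tibble(x))
  pick <- function(cols, default) {
    hit <- intersect(cols, names(x))
    if (length(hit) > 0) x[[hit[1]]] else default
  }
  out <- tibble(chrom = x$chrom, start = x$start, end = x$end,
                name = pick(c("name", "transcript_id", "locus_id",
                              "ar_id"), "."),
                score = pick(c("score", "gc"), 0),
                strand = pick("strand", "."))
  readr::write_tsv(out, path, col_names = FALSE)
  invisible(path)
}

#' Read a BED6 file
#'
#' @param path BED path.
#' @return Tibble `chrom`, `start`, `end`, `name`, `score`, `strand`.
#' @export
read_bed <- function(path) {
  x <- readr::read_tsv(path, col_names = FALSE, show_col_types = FALSE,
                       progress = FALSE)
  names(x)[seq_len(min(6, ncol(x)))] <-
    c("chrom", "start", "end", "name", "score", "strand")[seq_len(min(6, ncol(x)))]
  mutate(as_tibble(x), start = as.integer(.data$start),
         end = as.integer(.data$end))
}

#' Write peaks as narrowPeak
#'
#' Columns 7-9 (signal, p, q) are written as -1 placeholders; column 10
#' is the summit offset from the peak start.
#'
#' @param peaks Tibble `chrom`, `start`, `end`, `summit`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_narrowpeak <- function(peaks, path) {
  peaks <- validate_intervals(as_tibble(peaks))
  out <- tibble(chrom = peaks$chrom, start = peaks$start, end = peaks$end,
                name = sprintf("peak_%d", seq_len(nrow(peaks))),
                score = 0, strand = ".", signal = -1, p = -1, q = -1,
                summit_offset = peaks$summit - peaks$start)
  readr::write_tsv(out, path, col_names = FALSE)
  invisible(path)
}

#' Read a narrowPeak file
#'
#' @param path narrowPeak path.
#' @return Tibble `chrom`, `start`, `end`, `summit` (absolute).
#' @export
read_narrowpeak <- function(path) {
  x <- readr::read_tsv(path, col_names = FALSE, show_col_types = FALSE,
                       progress = FALSE)
  tibble(chrom = x[[1]], start = as.integer(x[[2]]),
         end = as.integer(x[[3]]),
         summit = as.integer(x[[2]] + x[[10]]))
}

#' Write gene models as GFF3
#'
#' Emits `gene` and `exon` features; internal 0-based half-open
#' coordinates are converted to GFF3's 1-based inclusive convention.
#'
#' @param gene_models Exon tibble with `gene_id`, `transcript_id`.
#' @param genes Gene-span tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gff3 <- function(gene_models, genes, path) {
  genes <- as_tibble(genes)
  gene_models <- as_tibble(gene_models)
  lines <- c("##gff-version 3",
             sprintf("%s\tlncturnover\tgene\t%d\t%d\t.\t%s\t.\tID=%s",
                     genes$chrom, genes$start + 1L, genes$end,
                     genes$strand, genes$gene_id),
             sprintf("%s\tlncturnover\texon\t%d\t%d\t.\t%s\t.\tParent=%s;transcript_id=%s",
                     gene_models$chrom, gene_models$start + 1L,
                     gene_models$end, gene_models$strand,
                     gene_models$gene_id, gene_models$transcript_id))
  writeLines(lines, path)
  invisible(path)
}

#' Read gene models from GFF3
#'
#' @param path GFF3 path (as written by \code{\link{write_gff3}} or any
#'   GFF3 with gene/exon rows carrying ID/Parent attributes).
#' @return List: `genes` (span tibble), `gene_models` (exon tibble),
#'   both 0-based half-open.
#' @export
read_gff3 <- function(path) {
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "#") & nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  get_attr <- function(attrs, key) {
    m <- regmatches(attrs, regexpr(paste0(key, "=[^;]+"), attrs))
    ifelse(lengths(regmatches(attrs, gregexpr(paste0(key, "="), attrs))) > 0,
           sub(paste0(key, "="), "", m), NA_character_)
  }
  tb <- tibble(chrom = map_chr(parts, 1), type = map_chr(parts, 3),
               start = as.integer(map_chr(parts, 4)) - 1L,
               end = as.integer(map_chr(parts, 5)),
               strand = map_chr(parts, 7), attrs = map_chr(parts, 9))
  genes <- filter(tb, .data$type == "gene")
  genes <- tibble(gene_id = get_attr(genes$attrs, "ID"),
                  chrom = genes$chrom, start = genes$start,
                  end = genes$end, strand = genes$strand)
  ex <- filter(tb, .data$type == "exon")
  gene_models <- tibble(gene_id = get_attr(ex$attrs, "Parent"),
                        transcript_id = get_attr(ex$attrs, "transcript_id"),
                        chrom = ex$chrom, start = ex$start, end = ex$end,
                        strand = ex$strand)
  list(genes = genes, gene_models = gene_models)
}

#' Write genome sequences as FASTA
#'
#' @param genome Named character vector / list of chromosome sequences.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_genome_fasta <- function(genome, path) {
  set <- Biostrings::DNAStringSet(unlist(genome))
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}

#' Read genome sequences from FASTA
#'
#' @param path FASTA path.
#' @return Named character vector of chromosome sequences.
#' @export
read_genome_fasta <- function(path) {
  set <- Biostrings::readDNAStringSet(path)
  setNames(as.character(set), names(set))
}

#' Write pairwise alignments as paired FASTA
#'
#' Two records per region, named `<region_id>|1` and `<region_id>|2`.
#'
#' @param alignments Tibble `region_id`, `seq1`, `seq2`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_alignments <- function(alignments, path) {
  alignments <- as_tibble(alignments)
  seqs <- c(rbind(alignments$seq1, alignments$seq2))
  nms <- c(rbind(paste0(alignments$region_id, "|1"),
                 paste0(alignments$region_id, "|2")))
  set <- Biostrings::DNAStringSet(setNames(seqs, nms))
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}

#' Read paired-FASTA alignments
#'
#' @param path Paired FASTA path (record pairs `id|1`, `id|2`).
#' @return Tibble `region_id`, `seq1`, `seq2`.
#' @export
read_alignments <- function(path) {
  set <- Biostrings::readDNAStringSet(path)
  nm <- names(set)
  rid <- sub("\\|[12]$", "", nm)
  which2 <- sub("^.*\\|", "", nm)
  s <- as.character(set)
  tibble(region_id = unique(rid),
         seq1 = s[which2 == "1"][match(unique(rid), rid[which2 == "1"])],
         seq2 = s[which2 == "2"][match(unique(rid), rid[which2 == "2"])])
}

#' Write / read a syntenic-block orthology map (TSV)
#'
#' Columns: `src_chrom src_start src_end tgt_chrom tgt_start
#' orientation`, 0-based half-open.
#'
#' @param map Orthology map tibble.
#' @param path TSV path.
#' @return `path` / the map tibble.
#' @export
write_orthology_map <- function(map, path) {
  readr::write_tsv(validate_orthology_map(map), path)
  invisible(path)
}

#' @rdname write_orthology_map
#' @export
read_orthology_map <- function(path) {
  map <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  map <- mutate(map, across(c("src_start", "src_end", "tgt_start"),
                            as.integer))
  validate_orthology_map(map)
}

#' Write a scenario bundle to a directory
#'
#' Emits the per-species file set (reads BED6, transfrags BED6, peaks
#' narrowPeak, genes GFF3, genome FASTA when present) plus the
#' cross-species files (ARs BED with G+C score, orthology map TSV,
#' counts TSV, ortholog/paralog/housekeeping TSVs, alignments paired
#' FASTA) and the planted-truth sidecar as JSON.
#'
#' @param scenario A \code{\link{generate_scenario}} bundle.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_scenario <- function(scenario, dir) {
  stopifnot(inherits(scenario, "lnc_scenario"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (sp in scenario$species) {
    write_bed(scenario$reads[[sp]], file.path(dir, paste0(sp, ".reads.bed")))
    write_bed(scenario$transfrags[[sp]],
              file.path(dir, paste0(sp, ".transfrags.bed")))
    write_narrowpeak(scenario$peaks[[sp]],
                     file.path(dir, paste0(sp, ".peaks.narrowPeak")))
    if (!is.null(scenario$genome)) {
      write_genome_fasta(scenario$genome[[sp]],
                         file.path(dir, paste0(sp, ".genome.fa")))
    }
  }
  write_gff3(scenario$gene_models, scenario$genes,
             file.path(dir, "genes.focal.gff3"))
  write_bed(scenario$ars, file.path(dir, "ancestral_repeats.bed"))
  write_orthology_map(scenario$orthology_map,
                      file.path(dir, "orthology_map.tsv"))
  readr::write_tsv(scenario$counts, file.path(dir, "counts.tsv"))
  readr::write_tsv(scenario$orthologs, file.path(dir, "orthologs.tsv"))
  readr::write_tsv(scenario$paralogs, file.path(dir, "paralogs.tsv"))
  writeLines(scenario$housekeeping, file.path(dir, "housekeeping.txt"))
  if (!is.null(scenario$alignments)) {
    write_alignments(scenario$alignments, file.path(dir, "alignments.fa"))
  }
  truth <- scenario$truth
  jsonlite::write_json(
    list(loci = truth$loci, rates = truth$rates, genes = truth$genes,
         library_scale = as.list(truth$library_scale)),
    file.path(dir, "truth.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
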