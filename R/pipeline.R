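#' Run the alien-specific SNP discovery pipeline end to end
#'
#' Executes QC -> mapping (independently against each of the three
#' homoeologous assemblies) -> pileup and variant calling -> depth/quality
#' filtering -> trio intersection with flank-identity and flank-cleanliness
#' filters -> marker export. All stages are deterministic functions of the
#' inputs and thresholds, so a rerun with identical inputs reproduces
#' byte-identical outputs.
#'
#' @param ref_a,ref_b,ref_d the three homoeologous assemblies (named
#'   character vectors, DNAStringSets or FASTA paths); `ref_a` is the
#'   anchor: alien-specific SNPs are reported on its coordinates.
#' @param reads raw alien-arm reads (data.frame `id`/`seq`/`qual`, or a
#'   FASTQ path).
#' @param alien_contigs optional alien assembly contigs for the
#'   flank-vs-alien concordance check.
#' @param annotation optional genic-interval table (`ref_id`, `start`,
#'   `end`) joined to anchor calls for the funnel's genic column.
#' @param out_dir optional output directory; when given, per-reference VCFs,
#'   the marker sheet (`markers.tsv`), flank FASTA, rejected-site TSV,
#'   candidate BED, QC and funnel TSVs and a JSON run manifest are written.
#' @param max_mismatch,min_depth,min_qual,flank_width,min_len,min_frac,qual_floor
#'   stage thresholds (defaults: 3 mismatches; depth >= 4; quality >= 50;
#'   100-bp flanks; length > 30; 80% of bases at phred >= 15).
#' @param marker_prefix marker id prefix.
#' @param write_sam also write per-reference SAM files (off by default; the
#'   alignments are large and reproducible).
#' @return (invisibly) list with `qc`, per-reference `mapping`, `coverage`,
#'   `raw_calls`, `filtered_calls`, the `sites`, `candidates`, `marker_sheet`,
#'   `funnel` and `manifest`.
#' @export
run_pipeline <- function(ref_a, ref_b, ref_d, reads, alien_contigs = NULL,
                         annotation = NULL, out_dir = NULL,
                         max_mismatch = 3L, min_depth = 4L, min_qual = 50,
                         flank_width = 100L, min_len = 30L, min_frac = 0.8,
                         qual_floor = 15L, marker_prefix = "gsnp_5ms",
                         write_sam = FALSE) {
  ref_a <- as_reference(ref_a)
  ref_b <- as_reference(ref_b)
  ref_d <- as_reference(ref_d)
  if (is.character(reads) && length(reads) == 1L) {
    if (!file.exists(reads)) stop("reads file not found: ", reads)
    reads <- read_fastq(reads)
  }
  if (!is.null(alien_contigs)) alien_contigs <- as_reference(alien_contigs)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  }

  qc <- qc_reads(reads, min_len = min_len, min_frac = min_frac,
                 qual_floor = qual_floor)
  clean <- qc$reads

  refs <- list(A = ref_a, B = ref_b, D = ref_d)
  mapping <- list()
  coverage <- list()
  raw_calls <- list()
  filtered_calls <- list()
  funnel <- list()
  for (g in names(refs)) {
    mp <- map_reads(clean, refs[[g]], max_mismatch = max_mismatch,
                    drop_ties = TRUE)
    cov <- coverage_summary(mp$alignments, refs[[g]], n_reads = nrow(clean))
    pu <- build_pileup(mp$alignments, clean, refs[[g]])
    raw <- call_raw_variants(pu)
    flt <- filter_variants(raw, min_depth = min_depth, min_qual = min_qual)
    genic <- NA_integer_
    if (!is.null(annotation) && g == "A") {
      flt <- label_genic(flt, annotation)
      genic <- sum(flt$genic)
    }
    mapping[[g]] <- mp
    coverage[[g]] <- cov
    raw_calls[[g]] <- raw
    filtered_calls[[g]] <- flt
    funnel[[g]] <- funnel_row(g, nrow(mp$alignments), raw, flt, genic)
    funnel[[g]]$snps_per_kb <- snp_density(flt, cov)
    if (!is.null(out_dir)) {
      write_vcf(flt, refs[[g]], file.path(out_dir,
                                          sprintf("calls_%s.vcf", g)))
      if (write_sam) {
        write_sam(mp$alignments, clean, refs[[g]],
                  file.path(out_dir, sprintf("aligned_%s.sam", g)))
      }
    }
  }
  funnel <- do.call(rbind, funnel)

  sites <- find_alien_specific(filtered_calls$A, filtered_calls$B,
                               filtered_calls$D, ref_a, ref_b, ref_d,
                               flank_width = flank_width,
                               emit_rejected = TRUE)
  candidates <- flank_clean_filter(sites, filtered_calls$A,
                                   alien_contigs = alien_contigs,
                                   flank_width = flank_width,
                                   prefix = marker_prefix)
  sheet <- NULL
  if (!is.null(out_dir)) {
    sheet <- export_marker_sheet(candidates,
                                 file.path(out_dir, "markers.tsv"),
                                 file.path(out_dir, "marker_flanks.fasta"))
    rejected <- sites[sites$reason != "", , drop = FALSE]
    write_tsv(rejected[, c("anchor_ref", "anchor_pos", "alien_allele",
                           "reason")],
              file.path(out_dir, "rejected_sites.tsv"))
    write_candidate_bed(candidates, file.path(out_dir, "candidates.bed"))
    write_tsv(qc$report, file.path(out_dir, "qc_report.tsv"))
    write_tsv(funnel, file.path(out_dir, "funnel.tsv"))
  } else {
    tmp <- tempfile(fileext = ".tsv")
    sheet <- export_marker_sheet(candidates, tmp)
    unlink(tmp)
  }

  manifest <- list(
    tool = "aliensnp",
    version = as.character(packageVersion("aliensnp")),
    parameters = list(max_mismatch = max_mismatch, min_depth = min_depth,
                      min_qual = min_qual, flank_width = flank_width,
                      min_len = min_len, min_frac = min_frac,
                      qual_floor = qual_floor,
                      marker_prefix = marker_prefix),
    counts = list(
      reads_in = qc$report$reads_in,
      reads_clean = qc$report$reads_kept,
      mapped_reads = lapply(mapping, function(m) nrow(m$alignments)),
      raw_snps = lapply(raw_calls, nrow),
      filtered_snps = lapply(filtered_calls, nrow),
      specific_sites = sum(sites$reason == ""),
      candidates = sum(candidates$status == "candidate")
    )
  )
  if (!is.null(out_dir)) {
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
  }
  invisible(list(qc = qc$report, mapping = mapping, coverage = coverage,
                 raw_calls = raw_calls, filtered_calls = filtered_calls,
                 sites = sites, candidates = candidates,
                 marker_sheet = sheet, funnel = funnel, manifest = manifest))
}

#' Run the pipeline from a key:value config file
#'
#' The config is YAML: keys `ref_a`, `ref_b`, `ref_d`, `reads` (paths;
#' required), `contigs`, `annotation`, `out_dir`, plus any of the threshold
#' parameters of [run_pipeline()].
#'
#' @param path YAML config file.
#' @export
run_pipeline_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  need <- c("ref_a", "ref_b", "ref_d", "reads")
  miss <- setdiff(need, names(cfg))
  if (length(miss)) stop("config missing required key(s): ",
                         paste(miss, collapse = ", "))
  for (key in c(need, intersect(c("contigs", "annotation"), names(cfg)))) {
    if (!file.exists(cfg[[key]])) {
      stop("config path does not exist: ", key, " = ", cfg[[key]])
    }
  }
  ann <- if (!is.null(cfg$annotation)) read_tsv(cfg$annotation) else NULL
  args <- list(ref_a = cfg$ref_a, ref_b = cfg$ref_b, ref_d = cfg$ref_d,
               reads = cfg$reads,
               alien_contigs = cfg$contigs, annotation = ann,
               out_dir = cfg$out_dir)
  opt <- intersect(names(cfg),
                   c("max_mismatch", "min_depth", "min_qual", "flank_width",
                     "min_len", "min_frac", "qual_floor", "marker_prefix",
                     "write_sam"))
  do.call(run_pipeline, c(args, cfg[opt]))
}
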