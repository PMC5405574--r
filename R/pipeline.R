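#' Write CRM predictions as BED6
#'
#' One BED record per CRM; `name` is the CRM key, `score` the LLR in
#' log2 units clamped to the BED 0-1000 range, `strand` is `"."` (CRMs
#' are strand-less; individual sites carry strand in the GFF3 output).
#'
#' @param pred A `crm_predictions` object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_crm_bed <- function(pred, path) {
  crms <- pred$crms
  df <- data.frame(chrom = crms$seq_id, start = crms$start,
                   end = crms$end, name = crms$crm_key,
                   score = round(pmin(pmax(crms$llr_log2, 0), 1000), 2),
                   strand = ".")
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read BED intervals into the package's interval layout
#'
#' @param path BED file path.
#' @return Data frame with `seq_id`, `start`, `end` (0-based half-open)
#'   and, when present, `name` and `score`.
#' @export
read_bed <- function(path) {
  gr <- rtracklayer::import(path, format = "BED")
  df <- data.frame(seq_id = as.character(GenomicRanges::seqnames(gr)),
                   start = GenomicRanges::start(gr) - 1L,
                   end = GenomicRanges::end(gr),
                   stringsAsFactors = FALSE)
  if (!is.null(gr$name)) df$name <- gr$name
  if (!is.null(gr$score)) df$score <- gr$score
  df
}

#' Write CRMs and their motif sites as GFF3
#'
#' CRMs become `CRM` features; their sites become child
#' `TF_binding_site` features with `Parent` attributes, motif id and
#' strand.
#'
#' @param pred A `crm_predictions` object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_sites_gff3 <- function(pred, path) {
  crms <- pred$crms; sites <- pred$sites
  gr_crm <- GenomicRanges::GRanges(
    seqnames = crms$seq_id,
    ranges = IRanges::IRanges(start = crms$start + 1L, end = crms$end),
    strand = "*",
    type = rep("CRM", nrow(crms)),
    ID = crms$crm_key,
    score = round(crms$llr, 4))
  gr_sites <- GenomicRanges::GRanges(
    seqnames = sites$seq_id,
    ranges = IRanges::IRanges(start = sites$start + 1L, end = sites$end),
    strand = sites$strand,
    type = rep("TF_binding_site", nrow(sites)),
    ID = paste0(sites$crm_key, ":site", seq_len(nrow(sites))),
    score = round(sites$log_odds, 4))
  gr_sites$Parent <- sites$crm_key
  gr_crm$Name <- crms$motifs
  gr_sites$Name <- sites$motif_id
  rtracklayer::export(c(gr_crm, gr_sites), path, format = "gff3")
  invisible(path)
}

#' Run the CRM discovery pipeline end-to-end
#'
#' Optional PWM redundancy filtering, background estimation, EM training,
#' Viterbi decoding with LLR scoring, weight filtering and conservation
#' screening; outputs are written to `out_dir` (model YAML, CRM BED6,
#' site GFF3, screening TSV, training trace TSV, manifest YAML).
#'
#' @param seqs Path to a FASTA file, or a named character vector of
#'   sequences.
#' @param pwms Path to a motif file, or a list of [pwm] objects.
#' @param out_dir Output directory (created if needed); `NULL` writes
#'   nothing.
#' @param pwm_format Motif file dialect when `pwms` is a path.
#' @param filter Run the optional PWM redundancy filter? Default `FALSE`.
#' @param p_r,q0,h,k,k_prime,z_threshold,E_threshold Model parameters,
#'   see [crm_model] and [estimate_backgrounds].
#' @param w_c,mu_m,crm_edge_threshold Screening parameters, see
#'   [screen_crms].
#' @param pwm_edge_threshold,pwm_density_threshold PWM filter thresholds,
#'   see [filter_pwms].
#' @param em Named list of EM settings (`max_iter`, `tol`, `burn_in`);
#'   see [em_fit].
#' @param seed Integer seed recorded in the manifest (the pipeline itself
#'   is deterministic).
#' @param verbose Log progress messages? Default `TRUE`.
#' @return List (invisibly when writing): `model`, `training`,
#'   `predictions` (screened `crm_predictions`), `filter_report`,
#'   `out_dir`.
#' @export
run_pipeline <- function(seqs, pwms, out_dir = NULL,
                         pwm_format = c("transfac", "jaspar"),
                         filter = FALSE,
                         p_r = 0.001, q0 = 0.1, h = 50,
                         k = 1L, k_prime = 2L,
                         z_threshold = 1, E_threshold = 1,
                         w_c = 0, mu_m = 0.5, crm_edge_threshold = 0.5,
                         pwm_edge_threshold = 0.8,
                         pwm_density_threshold = 0.7,
                         em = list(max_iter = 50L, tol = 1e-4,
                                   burn_in = 5L),
                         seed = 1L, verbose = TRUE) {
  pwm_format <- match.arg(pwm_format)
  say <- function(...) if (verbose) message("[crmscan] ", ...)
  input_paths <- character(0)
  if (is.character(seqs) && length(seqs) == 1L && file.exists(seqs)) {
    input_paths <- c(input_paths, sequences = seqs)
    seqs <- read_fasta(seqs)
  }
  if (is.character(pwms) && length(pwms) == 1L) {
    input_paths <- c(input_paths, motifs = pwms)
    pwms <- read_pwms(pwms, format = pwm_format)
  }
  if (length(seqs) == 0L) stop("no input sequences")
  if (length(pwms) == 0L) stop("no input PWMs")

  filter_report <- NULL
  if (filter) {
    say("filtering ", length(pwms), " PWMs")
    fl <- filter_pwms(pwms, edge_threshold = pwm_edge_threshold,
                      density_threshold = pwm_density_threshold)
    filter_report <- fl$report
    say("kept ", length(fl$pwms), " representative PWM(s)")
    pwms <- fl$pwms
  } else say("PWM filtering off; using all ", length(pwms), " PWM(s)")

  say("estimating background chains (orders ", k, ", ", k_prime, ")")
  bg <- estimate_backgrounds(seqs, k = k, k_prime = k_prime)
  model0 <- crm_model(pwms, theta0 = bg$theta0, theta1 = bg$theta1,
                      p_r = p_r, q0 = q0, h = h,
                      z_threshold = z_threshold, E_threshold = E_threshold)
  say("training on ", length(seqs), " sequence(s)")
  training <- em_fit(model0, seqs,
                     max_iter = em$max_iter %||% 50L,
                     tol = em$tol %||% 1e-4,
                     burn_in = em$burn_in %||% 5L,
                     verbose = FALSE)
  say("EM: ", training$iterations, " iteration(s), ",
      sum(lengths(training$model$corr)), " correlated pair(s)")
  model <- training$model

  say("decoding")
  pred <- predict_crms(model, seqs)
  say(nrow(pred$crms), " candidate CRM(s)")
  pred <- screen_crms(pred, n_sequences = length(seqs), w_c = w_c,
                      edge_threshold = crm_edge_threshold, mu_m = mu_m)
  say(if (pred$screened) paste0(length(pred$conserved_sets),
                                " conserved CRM set(s)")
      else "conservation screening skipped (<= 3 sequences with CRMs)")

  result <- list(model = model, training = training, predictions = pred,
                 filter_report = filter_report, out_dir = out_dir)
  if (is.null(out_dir)) return(result)

  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  written <- character(0)
  on.exit(if (length(written) > 0L && !finished) unlink(written),
          add = TRUE)
  finished <- FALSE
  wpath <- function(f) { p <- file.path(out_dir, f); written <<- c(written, p); p }
  write_crm_model(model, wpath("model.yaml"))
  write_crm_bed(pred, wpath("crms.bed"))
  write_sites_gff3(pred, wpath("sites.gff3"))
  utils::write.table(pred$crms, wpath("crms.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  sets_df <- if (length(pred$conserved_sets) > 0L) data.frame(
    set = seq_along(pred$conserved_sets),
    members = vapply(pred$conserved_sets, function(s)
      paste(s$members, collapse = ","), ""),
    conservation_score = vapply(pred$conserved_sets, `[[`, 0,
                                "conservation_score"))
  else data.frame(set = integer(), members = character(),
                  conservation_score = numeric())
  utils::write.table(sets_df, wpath("conserved_sets.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(
    data.frame(iteration = seq_along(training$loglik_trace) - 1L,
               loglik = training$loglik_trace),
    wpath("training_trace.tsv"), sep = "\t", quote = FALSE,
    row.names = FALSE)
  if (!is.null(filter_report))
    utils::write.table(filter_report, wpath("pwm_clusters.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  manifest <- list(
    package = "crmscan",
    version = as.character(utils::packageVersion("crmscan")),
    seed = seed,
    config = list(p_r = p_r, q0 = q0, h = h, k = k, k_prime = k_prime,
                  z_threshold = z_threshold, E_threshold = E_threshold,
                  w_c = w_c, mu_m = mu_m,
                  crm_edge_threshold = crm_edge_threshold,
                  filter = filter, em = em),
    inputs = if (length(input_paths) > 0L)
      as.list(vapply(input_paths, function(p)
        unname(tools::md5sum(p)), "")) else list(),
    n_sequences = length(seqs), n_pwms = length(pwms))
  yaml::write_yaml(manifest, wpath("manifest.yaml"))
  finished <- TRUE
  say("outputs written to ", out_dir)
  invisible(result)
}
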