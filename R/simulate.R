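#' Parameters of the synthetic M-factor screen scenario
#'
#' The simulator plants contigs of three linkage classes with the copy
#' numbers a hemizygous M locus implies — M-linked (male 1, female 0),
#' autosomal (2, 2) and female-dosage-biased (male 1, female 2) — and
#' emulates equal-depth male/female whole-genome sequencing plus a
#' developmental expression design with zygotic genome activation at
#' `activation_hour` (default 6.5 h post-oviposition, the onset of the
#' syncytial blastoderm stage), male-limited adult expression of the
#' planted M-linked contigs, and maternally deposited transcripts for the
#' other classes in 0–1 h embryos.
#'
#' @param n_m_linked,n_autosomal,n_female_biased contigs per linkage class
#'   (defaults 10, 200, 20).
#' @param length_range contig length interval in nt (default 1500–2000,
#'   mRNA-scale contigs of near-uniform length so per-contig coverage stays
#'   close to the nominal depth).
#' @param depth expected alignments per autosomal contig per sex at mean
#'   length (default 100).
#' @param leakage fraction of the autosomal depth leaking into the count of
#'   a sex with zero copies, e.g. from mismapping (default 0).
#' @param activation_hour zygotic activation time in hours post-oviposition
#'   (default 6.5); an embryonic stage whose collection window closes
#'   before this hour carries no zygotic transcripts.
#' @param expression_meanlog,expression_sdlog log-scale mean and sd of the
#'   per-contig baseline abundance (defaults log(50), 1).
#' @param replicate_sdlog log-scale sd of replicate-to-replicate noise
#'   (default 0.3).
#' @param female_bias_factor abundance multiplier of female-biased contigs
#'   in adult females (default 4).
#' @param replicates replicates per stage (default 3).
#' @param seed integer seed; all randomness derives from it.
#' @return validated parameter list of class `sim_params`.
#' @export
sim_params <- function(n_m_linked = 10, n_autosomal = 200, n_female_biased = 20,
                       length_range = c(1500, 2000), depth = 100, leakage = 0,
                       activation_hour = 6.5,
                       expression_meanlog = log(50), expression_sdlog = 1,
                       replicate_sdlog = 0.3, female_bias_factor = 4,
                       replicates = 3, seed) {
  if (missing(seed)) abort("`seed` is required")
  stopifnot_scalar_number(seed, "seed", integerish = TRUE)
  for (nm in c("n_m_linked", "n_autosomal", "n_female_biased")) {
    stopifnot_scalar_number(get(nm), nm, min = 0, integerish = TRUE)
  }
  if (n_m_linked + n_autosomal + n_female_biased == 0) {
    abort("at least one contig must be simulated")
  }
  if (length(length_range) != 2L || length_range[1] < 1 ||
      length_range[2] < length_range[1]) {
    abort("`length_range` must be an increasing positive interval")
  }
  stopifnot_scalar_number(depth, "depth")
  if (depth <= 0) abort("`depth` must be > 0")
  stopifnot_scalar_number(leakage, "leakage", min = 0)
  if (leakage >= 1) abort("`leakage` must be < 1")
  stopifnot_scalar_number(replicates, "replicates", min = 1, integerish = TRUE)
  structure(list(
    n_m_linked = n_m_linked, n_autosomal = n_autosomal,
    n_female_biased = n_female_biased,
    length_range = as.numeric(length_range), depth = depth, leakage = leakage,
    activation_hour = activation_hour,
    expression_meanlog = expression_meanlog,
    expression_sdlog = expression_sdlog,
    replicate_sdlog = replicate_sdlog,
    female_bias_factor = female_bias_factor,
    replicates = as.integer(replicates), seed = as.integer(seed)
  ), class = "sim_params")
}

# copy numbers implied by each linkage class: (male, female)
CLASS_COPIES <- list(M_linked = c(1, 0), autosomal = c(2, 2),
                     female_biased = c(1, 2))

#' Simulate a reference contig set with planted linkage classes
#'
#' @param params [sim_params()].
#' @return list with `references` (tibble `id`, `description`, `sequence`,
#'   `length`) and `truth` (tibble `id`, `class`, `copy_male`,
#'   `copy_female`, `length`) — the oracle for recovery tests. Sequences
#'   are uniform-composition DNA with lengths drawn uniformly from
#'   `length_range`; fully deterministic given the seed.
#' @export
simulate_reference_set <- function(params) {
  stopifnot(inherits(params, "sim_params"))
  n <- c(M_linked = params$n_m_linked, autosomal = params$n_autosomal,
         female_biased = params$n_female_biased)
  prefix <- c(M_linked = "M", autosomal = "auto", female_biased = "fbias")

  per_class <- purrr::imap(n, function(count, cls) {
    if (count == 0L) return(NULL)
    # one substream per class so class sizes do not perturb each other
    with_substream(params$seed, match(cls, names(n)) * 1000L, {
      len <- floor(runif(count, params$length_range[1], params$length_range[2] + 1))
      seqs <- vapply(len, function(L) {
        paste(sample(c("A", "C", "G", "T"), L, replace = TRUE), collapse = "")
      }, character(1))
      tibble(id = sprintf("%s_%04d", prefix[[cls]], seq_len(count)),
             class = cls, sequence = seqs, length = as.integer(len))
    })
  })
  all <- bind_rows(per_class)
  list(
    references = tibble(id = all$id,
                        description = paste("simulated", all$class, "contig"),
                        sequence = all$sequence, length = all$length),
    truth = tibble(id = all$id, class = all$class,
                   copy_male = vapply(all$class, function(c) CLASS_COPIES[[c]][1], numeric(1)),
                   copy_female = vapply(all$class, function(c) CLASS_COPIES[[c]][2], numeric(1)),
                   length = all$length)
  )
}

#' Simulate male/female genomic alignment counts
#'
#' Per contig and sex, the count is Poisson with mean
#' `depth * copy_number/2 * length/mean_length`; for a sex with zero
#' copies, the mean is `leakage * depth` (mismapping leakage, 0 by
#' default, giving exact zeros). Library totals are the column sums plus a
#' constant off-target mass, so totals always exceed the tabulated counts.
#'
#' @param truth truth table from [simulate_reference_set()].
#' @param params [sim_params()].
#' @param off_target_mass constant added to each library total
#'   (default 1e6).
#' @return a `count_table` (see [read_count_table()]).
#' @export
simulate_dna_counts <- function(truth, params, off_target_mass = 1e6) {
  stopifnot(inherits(params, "sim_params"))
  assert_columns(truth, c("id", "class", "copy_male", "copy_female", "length"),
                 "truth table")
  lenf <- truth$length / mean(truth$length)
  mean_for <- function(copy) {
    ifelse(copy == 0, params$leakage * params$depth,
           params$depth * copy / 2 * lenf)
  }
  male <- with_substream(params$seed, 101L,
                         rpois(nrow(truth), mean_for(truth$copy_male)))
  female <- with_substream(params$seed, 102L,
                           rpois(nrow(truth), mean_for(truth$copy_female)))
  new_count_table(
    tibble(id = truth$id, male_count = male, female_count = female),
    male_total = sum(male) + off_target_mass,
    female_total = sum(female) + off_target_mass
  )
}

#' Simulate a stage-resolved expression matrix
#'
#' Emulates the developmental design of the screen: every stage in
#' `replicates` replicates. M-linked contigs are exactly zero in all
#' samples collected before zygotic activation and in adult females, and
#' positive (log-normal around the contig baseline) from activation
#' onward in male-containing samples — the transcript signature of an
#' early-acting, male-limited M factor. Autosomal contigs are positive in
#' every sample (maternal deposition covers the earliest embryos);
#' female-biased contigs are additionally elevated in adult females.
#'
#' @param truth truth table from [simulate_reference_set()].
#' @param params [sim_params()].
#' @param stages stages to include (default all seven).
#' @return raw expression table (`ref_id` + sample columns, sample sheet
#'   attached; see [sample_sheet()]).
#' @export
simulate_expression_matrix <- function(truth, params, stages = STAGE_LEVELS) {
  stopifnot(inherits(params, "sim_params"))
  needed <- c("E0_1h", "E4_8h", "E8_12h", "adult_female")
  if (!all(needed %in% stages)) {
    warn(sprintf("design lacks stage(s) used by the default filter: %s",
                 paste(setdiff(needed, stages), collapse = ", ")))
  }
  sheet <- tidyr::expand_grid(stage = stages,
                              replicate = seq_len(params$replicates)) |>
    mutate(sample_id = sprintf("%s_r%d", .data$stage, .data$replicate)) |>
    select(all_of(c("sample_id", "stage", "replicate")))

  n_ref <- nrow(truth)
  baseline <- with_substream(params$seed, 201L,
                             rlnorm(n_ref, params$expression_meanlog,
                                    params$expression_sdlog))
  noise <- with_substream(params$seed, 202L,
                          matrix(rlnorm(n_ref * nrow(sheet), 0,
                                        params$replicate_sdlog),
                                 nrow = n_ref))
  vals <- baseline * noise

  pre_activation <- STAGE_END_HOURS[sheet$stage] < params$activation_hour
  for (j in seq_len(nrow(sheet))) {
    st <- sheet$stage[j]
    m_silent <- pre_activation[j] || st == "adult_female"
    if (m_silent) vals[truth$class == "M_linked", j] <- 0
    if (st == "adult_female") {
      vals[truth$class == "female_biased", j] <-
        vals[truth$class == "female_biased", j] * params$female_bias_factor
    }
  }
  colnames(vals) <- sheet$sample_id
  new_expression(bind_cols(tibble(ref_id = truth$id), as_tibble(vals)),
                 sheet, normalized = FALSE)
}

#' Simulate a complete screen scenario in memory
#'
#' @param params [sim_params()].
#' @return list with `references`, `truth`, `counts` (a `count_table`) and
#'   `expression` (raw expression table with sample sheet attached).
#' @examples
#' sc <- simulate_scenario(sim_params(n_m_linked = 2, n_autosomal = 20, seed = 1))
#' names(sc)
#' @export
simulate_scenario <- function(params) {
  refset <- simulate_reference_set(params)
  list(references = refset$references, truth = refset$truth,
       counts = simulate_dna_counts(refset$truth, params),
       expression = simulate_expression_matrix(refset$truth, params))
}

#' Write a simulated scenario bundle to disk
#'
#' Materialises [simulate_scenario()] as plain-text files — reference
#' FASTA, count TSV, raw expression TSV, sample sheet TSV, truth TSV — plus
#' a YAML manifest recording every parameter (including the seed and the
#' library totals), so the bundle regenerates and re-reads exactly.
#'
#' @param dir output directory.
#' @param params [sim_params()].
#' @param force overwrite an existing non-empty directory (default FALSE;
#'   otherwise an error).
#' @return named character vector of the paths written, invisibly; the
#'   scenario list itself as attribute `scenario`.
#' @export
make_scenario <- function(dir, params, force = FALSE) {
  if (dir.exists(dir) && length(dir(dir)) > 0L && !force) {
    abort(sprintf("output dir %s exists and is not empty (use force = TRUE)", dir))
  }
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  sc <- simulate_scenario(params)
  paths <- c(
    fasta = file.path(dir, "references.fa"),
    counts = file.path(dir, "counts.tsv"),
    matrix = file.path(dir, "expression.tsv"),
    samples = file.path(dir, "samples.tsv"),
    truth = file.path(dir, "truth.tsv"),
    manifest = file.path(dir, "manifest.yaml")
  )
  write_fasta(sc$references, paths[["fasta"]])
  readr::write_tsv(as_tibble(sc$counts), paths[["counts"]])
  readr::write_tsv(as_tibble(sc$expression), paths[["matrix"]])
  readr::write_tsv(sample_sheet(sc$expression), paths[["samples"]])
  readr::write_tsv(sc$truth, paths[["truth"]])
  yaml::write_yaml(c(unclass(params),
                     list(male_total = attr(sc$counts, "male_total"),
                          female_total = attr(sc$counts, "female_total"))),
                   paths[["manifest"]])
  invisible(structure(paths, scenario = sc))
}

#' Read a scenario bundle written by [make_scenario()]
#'
#' @param dir scenario directory.
#' @return list with `references`, `truth`, `counts`, `expression` and
#'   `params` (the manifest contents).
#' @export
read_scenario <- function(dir) {
  manifest <- yaml::read_yaml(file.path(dir, "manifest.yaml"))
  truth <- readr::read_tsv(file.path(dir, "truth.tsv"), show_col_types = FALSE)
  list(
    references = read_fasta(file.path(dir, "references.fa")),
    truth = truth,
    counts = read_count_table(file.path(dir, "counts.tsv"),
                              male_total = manifest$male_total,
                              female_total = manifest$female_total),
    expression = read_expression(file.path(dir, "expression.tsv"),
                                 file.path(dir, "samples.tsv")),
    params = manifest
  )
}
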