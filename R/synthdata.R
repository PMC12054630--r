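# Synthetic dual-species single-cell data with a planted anchor-correlated
# stress program, a partial homolog map, and a synthetic clinical table.
# The distributional choices (gamma latent stress, log-normal library size,
# negative-binomial counts) are explicit stand-ins for real data: the screen
# this package implements was designed for public atlas data whose
# generative process is unknown.

#' Simulation configuration
#'
#' Bundles every knob of the synthetic-data module and validates it once.
#' Defaults describe a two-species cardiac scenario: three cell types
#' (cardiomyocytes CM, fibroblasts FB, endothelial cells EC), a
#' control/stressed contrast, an `Nppa`-like anchor with a planted
#' co-regulated program that loads only in CM cells, a partial homolog map
#' (default fraction 0.88), and a 95-subject clinical table with 42
#' covariates of which 3 are truly associated with target expression.
#'
#' @param n_genes Total number of genes per species (anchor included).
#' @param n_cells_per_group Cells per (cell_type, condition) combination.
#' @param cell_types Cell-type labels; the first entry receives the stress
#'   program (default `c("CM","FB","EC")`).
#' @param conditions Condition labels, exactly two; the second is the
#'   stressed one (default `c("control","stressed")`).
#' @param anchor_id Label of the anchor gene.
#' @param n_planted Number of genes co-regulated with the anchor.
#' @param effect_size Change in natural-log mean expression per unit latent
#'   stress score, applied to the anchor and planted genes in CM cells.
#'   Must be >= 0; 0 means no planted signal.
#' @param stress_shift Difference in mean latent stress score between
#'   stressed and control cells (control mean is 1).
#' @param baseline_logmean_range Interval from which each gene's baseline
#'   natural-log mean count is drawn uniformly.
#' @param dispersion Negative-binomial inverse-size parameter phi
#'   (variance = mu + phi mu^2); a scalar, or a length-2 range sampled
#'   per gene. Must be > 0.
#' @param libsize_sigma Standard deviation of the log-normal per-cell
#'   library-size factor.
#' @param homolog_fraction Probability that a gene has a cross-species
#'   homolog (default 0.88, i.e. 44 of 50 genes mappable in expectation).
#' @param n_subjects Rows of the synthetic clinical table (>= 10).
#' @param n_covariates Clinical covariates (default 42).
#' @param n_true_covariates Covariates truly associated with the target.
#' @param true_coef Coefficient linking target expression to each true
#'   covariate (covariate = true_coef * target + standard normal noise).
#' @param seed Master seed; all stage-level seeds derive from it.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(n_genes = 2000L,
                       n_cells_per_group = 200L,
                       cell_types = c("CM", "FB", "EC"),
                       conditions = c("control", "stressed"),
                       anchor_id = "Nppa",
                       n_planted = 30L,
                       effect_size = 1.0,
                       stress_shift = 1.0,
                       baseline_logmean_range = c(-3, 1),
                       dispersion = 0.5,
                       libsize_sigma = 0.3,
                       homolog_fraction = 0.88,
                       n_subjects = 95L,
                       n_covariates = 42L,
                       n_true_covariates = 3L,
                       true_coef = 0.5,
                       seed = 1L) {
  cfg <- list(
    n_genes = as.integer(n_genes),
    n_cells_per_group = as.integer(n_cells_per_group),
    cell_types = as.character(cell_types),
    conditions = as.character(conditions),
    anchor_id = as.character(anchor_id),
    n_planted = as.integer(n_planted),
    effect_size = as.double(effect_size),
    stress_shift = as.double(stress_shift),
    baseline_logmean_range = as.double(baseline_logmean_range),
    dispersion = as.double(dispersion),
    libsize_sigma = as.double(libsize_sigma),
    homolog_fraction = as.double(homolog_fraction),
    n_subjects = as.integer(n_subjects),
    n_covariates = as.integer(n_covariates),
    n_true_covariates = as.integer(n_true_covariates),
    true_coef = as.double(true_coef),
    seed = as.integer(seed)
  )
  if (cfg$n_genes < 2L) stop_fmt("n_genes must be at least 2")
  if (cfg$n_planted < 0L || cfg$n_planted >= cfg$n_genes)
    stop_fmt("n_planted (%d) must be in [0, n_genes)", cfg$n_planted)
  if (cfg$n_cells_per_group < 1L) stop_fmt("n_cells_per_group must be >= 1")
  if (length(cfg$conditions) != 2L)
    stop_fmt("exactly two conditions are required")
  if (cfg$effect_size < 0) stop_fmt("effect_size must be >= 0")
  if (any(cfg$dispersion <= 0)) stop_fmt("dispersion must be > 0")
  if (!length(cfg$dispersion) %in% c(1L, 2L))
    stop_fmt("dispersion must be a scalar or a length-2 range")
  if (cfg$libsize_sigma < 0) stop_fmt("libsize_sigma must be >= 0")
  if (cfg$homolog_fraction < 0 || cfg$homolog_fraction > 1)
    stop_fmt("homolog_fraction must lie in [0, 1]")
  if (length(cfg$baseline_logmean_range) != 2L ||
      diff(cfg$baseline_logmean_range) < 0)
    stop_fmt("baseline_logmean_range must be a non-decreasing interval")
  if (cfg$n_true_covariates > cfg$n_covariates)
    stop_fmt("n_true_covariates cannot exceed n_covariates")
  if (cfg$stress_shift < 0) stop_fmt("stress_shift must be >= 0")
  class(cfg) <- "sim_config"
  cfg
}

sim_gene_labels <- function(cfg) {
  width <- max(4L, nchar(as.character(cfg$n_genes)))
  others <- sprintf(paste0("gene%0", width, "d"), seq_len(cfg$n_genes - 1L))
  c(cfg$anchor_id, others)
}

#' Simulate one species' single-cell dataset
#'
#' Generative model, per cell i: a latent stress score s_i drawn from a
#' Gamma(shape 2) distribution whose mean is 1 for control cells and
#' 1 + `stress_shift` for stressed cells; outside the stress-bearing cell
#' type (the first entry of `cell_types`) s_i is fixed at its condition
#' mean so that all stress variation lives in that cell type. A library
#' factor L_i is LogNormal(0, `libsize_sigma`). Per gene g a baseline log
#' mean beta_g is uniform on `baseline_logmean_range`; the log mean is
#' beta_g + `effect_size` * s_i for the anchor and planted genes in
#' stress-bearing cells and beta_g otherwise. Counts are negative binomial
#' with mean L_i * exp(log mean) and variance mu + phi mu^2. Deterministic
#' given `cfg$seed` and `stage`.
#'
#' @param cfg A [sim_config()].
#' @param species_tag Label stored in the metadata and prefixed to barcodes.
#' @param stage Integer stage index used to derive the child seed; give the
#'   two species of a pair different stages for independent noise.
#' @return A list with `counts` (sparse gene x cell dgCMatrix), `meta`
#'   (data.frame: barcode, species, cell_type, condition, sample_id) and
#'   `truth` (class `anchor_truth`: anchor, planted genes, per-cell stress
#'   scores, effect size).
#' @export
simulate_species <- function(cfg, species_tag = "mouse", stage = 1L) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(child_seed(cfg$seed, stage))

  genes <- sim_gene_labels(cfg)
  planted <- if (cfg$n_planted > 0L) genes[1L + seq_len(cfg$n_planted)] else character()

  grid <- expand.grid(condition = cfg$conditions, cell_type = cfg$cell_types,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  cell_type <- rep(grid$cell_type, each = cfg$n_cells_per_group)
  condition <- rep(grid$condition, each = cfg$n_cells_per_group)
  n_cells <- length(cell_type)
  barcodes <- sprintf("%s_%s_%s_%05d", species_tag, cell_type, condition,
                      seq_len(n_cells))
  sample_id <- sprintf("%s_%s_s%d", species_tag, condition,
                       1L + seq_len(n_cells) %% 2L)

  stressed_label <- cfg$conditions[2L]
  cond_mean <- ifelse(condition == stressed_label, 1 + cfg$stress_shift, 1)
  stress_ct <- cfg$cell_types[1L]
  in_ct <- cell_type == stress_ct
  stress <- cond_mean
  stress[in_ct] <- rgamma(sum(in_ct), shape = 2, scale = cond_mean[in_ct] / 2)
  names(stress) <- barcodes

  lib <- rlnorm(n_cells, meanlog = 0, sdlog = cfg$libsize_sigma)
  beta <- runif(cfg$n_genes, cfg$baseline_logmean_range[1L],
                cfg$baseline_logmean_range[2L])
  phi <- if (length(cfg$dispersion) == 2L)
    runif(cfg$n_genes, cfg$dispersion[1L], cfg$dispersion[2L])
  else rep(cfg$dispersion, cfg$n_genes)

  mu <- tcrossprod(exp(beta), lib)           # genes x cells baseline means
  sig_rows <- match(c(cfg$anchor_id, planted), genes)
  if (cfg$effect_size > 0 && any(in_ct)) {
    boost <- exp(cfg$effect_size * stress[in_ct])
    mu[sig_rows, in_ct] <- mu[sig_rows, in_ct] *
      rep(boost, each = length(sig_rows))
  }
  counts <- matrix(
    rnbinom(length(mu), mu = as.vector(mu), size = rep(1 / phi, times = n_cells)),
    nrow = cfg$n_genes, ncol = n_cells,
    dimnames = list(genes, barcodes)
  )
  counts <- Matrix::Matrix(counts, sparse = TRUE)

  meta <- data.frame(
    barcode = barcodes, species = species_tag, cell_type = cell_type,
    condition = condition, sample_id = sample_id, stringsAsFactors = FALSE
  )
  truth <- structure(list(
    anchor = cfg$anchor_id,
    planted_genes = planted,
    stress = stress,
    effect_size = cfg$effect_size
  ), class = "anchor_truth")
  list(counts = counts, meta = meta, truth = truth)
}

#' Simulate a paired-species dataset with a shared planted program
#'
#' Runs [simulate_species()] twice with independent noise (different child
#' seeds) but the same planted-gene identities: the premise being emulated
#' is a stress program conserved across species. Species-B gene labels are
#' the uppercase transform of species-A labels (the mouse-to-human symbol
#' convention); a homolog pair is emitted for each gene independently with
#' probability `homolog_fraction`.
#'
#' @param cfg A [sim_config()].
#' @param tags Length-2 character vector of species labels.
#' @return A list with `a`, `b` (each as [simulate_species()] returns, with
#'   species-B labels uppercased), `homologs` (data.frame gene_a/gene_b),
#'   and `truth` combining both species' ground truth plus the homolog map.
#' @export
simulate_pair <- function(cfg, tags = c("mouse", "human")) {
  stopifnot(inherits(cfg, "sim_config"), length(tags) == 2L)
  a <- simulate_species(cfg, species_tag = tags[1L], stage = 1L)
  b <- simulate_species(cfg, species_tag = tags[2L], stage = 2L)

  genes_a <- rownames(a$counts)
  genes_b <- toupper(genes_a)
  rownames(b$counts) <- genes_b
  b$truth$anchor <- toupper(b$truth$anchor)
  b$truth$planted_genes <- toupper(b$truth$planted_genes)

  set.seed(child_seed(cfg$seed, 3L))
  keep <- runif(cfg$n_genes) < cfg$homolog_fraction
  homologs <- data.frame(gene_a = genes_a[keep], gene_b = genes_b[keep],
                         stringsAsFactors = FALSE)

  truth <- structure(list(
    anchor = c(a = a$truth$anchor, b = b$truth$anchor),
    planted_genes = list(a = a$truth$planted_genes,
                         b = b$truth$planted_genes),
    homolog_pairs = homologs,
    stress = list(a = a$truth$stress, b = b$truth$stress),
    effect_size = cfg$effect_size
  ), class = "anchor_truth")
  list(a = a, b = b, homologs = homologs, truth = truth)
}

#' Simulate a subject-level clinical table
#'
#' Target expression is standard normal across `n_subjects` subjects. Each
#' true covariate equals `true_coef` times the target plus standard normal
#' noise; null covariates are independent standard normal. Column names are
#' unique (`cov01`, `cov02`, ...), the target column is `target_expr`.
#'
#' @param cfg A [sim_config()].
#' @return A list with `clinical` (data.frame: subject_id, covariates,
#'   target_expr) and `truth` (true covariate names and coefficients).
#' @export
simulate_clinical <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  if (cfg$n_subjects < 10L) stop_fmt("n_subjects must be at least 10")
  set.seed(child_seed(cfg$seed, 4L))
  n <- cfg$n_subjects
  y <- rnorm(n)
  width <- max(2L, nchar(as.character(cfg$n_covariates)))
  cov_names <- sprintf(paste0("cov%0", width, "d"), seq_len(cfg$n_covariates))
  true_names <- head(cov_names, cfg$n_true_covariates)
  covs <- vapply(cov_names, function(nm) {
    if (nm %in% true_names) cfg$true_coef * y + rnorm(n) else rnorm(n)
  }, numeric(n))
  clinical <- data.frame(subject_id = sprintf("S%03d", seq_len(n)),
                         covs, target_expr = y,
                         stringsAsFactors = FALSE, check.names = FALSE)
  truth <- structure(list(
    true_covariates = true_names,
    coefficients = setNames(rep(cfg$true_coef, length(true_names)), true_names)
  ), class = "anchor_truth")
  list(clinical = clinical, truth = truth)
}

#' Serialize / restore ground truth
#'
#' Ground truth round-trips through JSON unchanged (up to double precision),
#' so a simulation's answer key can live next to its on-disk bundle.
#'
#' @param truth An `anchor_truth` object.
#' @param path File path for the JSON document.
#' @return `write_truth` returns `path` invisibly; `read_truth` returns the
#'   restored `anchor_truth`.
#' @export
write_truth <- function(truth, path) {
  stopifnot(inherits(truth, "anchor_truth"))
  payload <- unclass(truth)
  # named numeric vectors -> explicit {names, values} so JSON keeps them
  payload <- rapply(payload, function(x) {
    if (!is.null(names(x)))
      list(.names = names(x), .values = unname(x))
    else x
  }, how = "replace", classes = c("numeric", "integer", "character"))
  jsonlite::write_json(payload, path, auto_unbox = FALSE, digits = NA,
                       dataframe = "columns")
  invisible(path)
}

#' @rdname write_truth
#' @export
read_truth <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  restore <- function(x) {
    if (is.list(x) && identical(sort(names(x)), c(".names", ".values")))
      return(setNames(x$.values, x$.names))
    if (is.data.frame(x)) return(x)
    if (is.list(x)) return(lapply(x, restore))
    x
  }
  out <- restore(raw)
  if (!is.null(out$homolog_pairs))
    out$homolog_pairs <- as.data.frame(out$homolog_pairs,
                                       stringsAsFactors = FALSE)
  structure(out, class = "anchor_truth")
}
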