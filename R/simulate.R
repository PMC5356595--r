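#' Simulation configuration for TCGA-like isoform expression data
#'
#' Builds a validated configuration for [simulate_dataset()]. Defaults emulate
#' a five-subtype breast-cancer cohort with unbalanced group sizes (discovery
#' n = 451, validation n = 463), multi-isoform genes, overdispersed FPKM-like
#' values with structural zeros and occasional extreme multiplicative
#' outliers, and planted single-subtype plus pairwise co-expression markers.
#'
#' @param n_subtypes number of subtype groups (>= 2).
#' @param samples_per_subtype either a numeric vector of per-subtype sample
#'   counts used for both splits, or a list with elements `discovery` and
#'   `validation`.
#' @param n_genes number of genes simulated.
#' @param isoforms_per_gene either a single fixed integer or a probability
#'   vector over 1..k isoforms per gene.
#' @param baseline_mean median baseline expression (FPKM scale); per-isoform
#'   baselines are drawn log-normally around it (sdlog = 1).
#' @param dispersion_phi quasi-Poisson variance inflation `Var = phi * mean`
#'   (>= 1).
#' @param zero_rate probability an entry is replaced by a structural zero.
#' @param outlier_rate probability an entry is multiplied by `outlier_scale`.
#' @param outlier_scale multiplicative outlier size.
#' @param n_specific planted single-subtype markers per subtype.
#' @param n_coexpressed planted markers per subtype pair (both pair members
#'   elevated by the same fold).
#' @param effect_fold fold change of planted markers (> 1).
#' @param seed integer seed; the whole dataset is reproducible from it.
#' @return object of class `sim_config` (a validated list).
#' @export
simulation_config <- function(n_subtypes = 5,
                              samples_per_subtype = list(
                                discovery  = c(77, 30, 231, 93, 20),
                                validation = c(79, 31, 237, 95, 21)),
                              n_genes = 400,
                              isoforms_per_gene = c(0.40, 0.25, 0.15, 0.10, 0.06, 0.04),
                              baseline_mean = 20,
                              dispersion_phi = 20,
                              zero_rate = 0.15,
                              outlier_rate = 0.005,
                              outlier_scale = 50,
                              n_specific = 10,
                              n_coexpressed = 3,
                              effect_fold = 8,
                              seed = 1L) {
  if (n_subtypes < 2) stop("need at least 2 subtypes")
  if (!is.list(samples_per_subtype))
    samples_per_subtype <- list(discovery = samples_per_subtype,
                                validation = samples_per_subtype)
  for (sp in samples_per_subtype) {
    if (length(sp) != n_subtypes) stop("samples_per_subtype length must equal n_subtypes")
    if (any(sp < 2)) stop("each subtype needs >= 2 samples per split")
  }
  if (length(isoforms_per_gene) == 1L) {
    k <- as.integer(isoforms_per_gene)
    if (k < 1) stop("isoforms_per_gene must be >= 1")
    isoforms_per_gene <- c(rep(0, k - 1L), 1)
  }
  if (any(isoforms_per_gene < 0) || sum(isoforms_per_gene) <= 0)
    stop("isoforms_per_gene must be a non-negative probability vector")
  isoforms_per_gene <- isoforms_per_gene / sum(isoforms_per_gene)
  for (r in c(zero_rate, outlier_rate))
    if (r < 0 || r > 1) stop("rates must lie in [0, 1]")
  if (effect_fold <= 1) stop("effect_fold must exceed 1")
  if (dispersion_phi < 1) stop("dispersion_phi must be >= 1")
  if (baseline_mean <= 0 || outlier_scale <= 0) stop("scales must be positive")
  cfg <- list(n_subtypes = n_subtypes, samples_per_subtype = samples_per_subtype,
              n_genes = n_genes, isoforms_per_gene = isoforms_per_gene,
              baseline_mean = baseline_mean, dispersion_phi = dispersion_phi,
              zero_rate = zero_rate, outlier_rate = outlier_rate,
              outlier_scale = outlier_scale, n_specific = n_specific,
              n_coexpressed = n_coexpressed, effect_fold = effect_fold,
              seed = as.integer(seed))
  class(cfg) <- "sim_config"
  cfg
}

# draw a features x samples block with E = mu, Var = phi * mu per entry.
# Gamma(shape = mu/phi, scale = phi) has exactly this moment pair on
# continuous support, matching FPKM-like data.
rquasipois <- function(mu, phi) {
  x <- stats::rgamma(length(mu), shape = as.vector(mu) / phi, scale = phi)
  dim(x) <- dim(mu)
  x
}

subtype_names <- function(n) {
  base <- c("Basal", "Her2", "LumA", "LumB", "Normal")
  if (n <= length(base)) base[seq_len(n)] else c(base, paste0("S", seq_len(n - length(base))))
}

#' Simulate an isoform expression dataset with planted subtype patterns
#'
#' Draws discovery and validation splits independently from the same planted
#' truth. Per isoform i and subtype g the mean is `mu_ig = b_i * f_ig` where
#' `b_i` is the isoform baseline and `f_ig` is `effect_fold` in planted
#' subtype(s) and 1 elsewhere; values are drawn with `Var = phi * mean`,
#' then structural zeros and multiplicative outliers are applied.
#'
#' @param cfg a [simulation_config()] object.
#' @return list with elements
#'   \describe{
#'     \item{expression}{isoform x sample matrix over both splits}
#'     \item{samples}{sample annotation (`sample_id`, `subtype`, `split`)}
#'     \item{annotation}{transcript annotation (`isoform_id`, `gene_id`,
#'       `is_coding`, `length_nt`)}
#'     \item{truth}{planted truth per isoform (`isoform_id`, `pattern` in
#'       specific/coexpressed/null, `subtype`, `subtype2`, `effect_fold`)}
#'   }
#' @export
simulate_dataset <- function(cfg = simulation_config()) {
  if (!inherits(cfg, "sim_config")) stop("cfg must come from simulation_config()")
  old <- if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(cfg$seed)

  G <- cfg$n_subtypes
  subtypes <- subtype_names(G)

  # gene/isoform structure
  ipg <- sample.int(length(cfg$isoforms_per_gene), cfg$n_genes,
                    replace = TRUE, prob = cfg$isoforms_per_gene)
  gene_ids <- sprintf("G%04d", seq_len(cfg$n_genes))
  iso_gene <- rep(gene_ids, ipg)
  n_iso <- length(iso_gene)
  iso_ids <- sprintf("%s.%d", iso_gene, unlist(lapply(ipg, seq_len)))

  # planted truth: distinct isoforms per pattern
  pairs <- if (G >= 3) utils::combn(G, 2) else matrix(nrow = 2, ncol = 0)
  need <- cfg$n_specific * G + cfg$n_coexpressed * ncol(pairs)
  if (need > n_iso)
    stop("infeasible config: ", need, " planted markers but only ", n_iso, " isoforms")
  planted <- sample.int(n_iso, need)
  truth <- data.frame(isoform_id = iso_ids, pattern = "null",
                      subtype = NA_character_, subtype2 = NA_character_,
                      effect_fold = 1, stringsAsFactors = FALSE)
  at <- 0L
  fold_mat <- matrix(1, n_iso, G, dimnames = list(iso_ids, subtypes))
  for (g in seq_len(G)) {
    idx <- planted[at + seq_len(cfg$n_specific)]; at <- at + cfg$n_specific
    truth$pattern[idx] <- "specific"
    truth$subtype[idx] <- subtypes[g]
    truth$effect_fold[idx] <- cfg$effect_fold
    fold_mat[idx, g] <- cfg$effect_fold
  }
  for (p in seq_len(ncol(pairs))) {
    idx <- planted[at + seq_len(cfg$n_coexpressed)]; at <- at + cfg$n_coexpressed
    truth$pattern[idx] <- "coexpressed"
    truth$subtype[idx] <- subtypes[pairs[1, p]]
    truth$subtype2[idx] <- subtypes[pairs[2, p]]
    truth$effect_fold[idx] <- cfg$effect_fold
    fold_mat[idx, pairs[, p]] <- cfg$effect_fold
  }

  baseline <- cfg$baseline_mean * stats::rlnorm(n_iso, meanlog = 0, sdlog = 1)

  draw_split <- function(split) {
    sizes <- cfg$samples_per_subtype[[split]]
    subtype <- rep(subtypes, sizes)
    n <- length(subtype)
    ids <- sprintf("%s_%04d", substr(split, 1, 4), seq_len(n))
    mu <- (baseline * fold_mat)[, match(subtype, subtypes), drop = FALSE]
    x <- rquasipois(mu, cfg$dispersion_phi)
    if (cfg$zero_rate > 0)
      x[stats::runif(length(x)) < cfg$zero_rate] <- 0
    if (cfg$outlier_rate > 0) {
      hit <- stats::runif(length(x)) < cfg$outlier_rate
      x[hit] <- x[hit] * cfg$outlier_scale
    }
    dimnames(x) <- list(iso_ids, ids)
    list(x = x, samples = data.frame(sample_id = ids, subtype = subtype,
                                     split = split, stringsAsFactors = FALSE))
  }
  disc <- draw_split("discovery")
  vali <- draw_split("validation")

  # annotation: ~75% coding; non-coding lengths straddle the 200 nt biotype cut
  is_coding <- stats::runif(n_iso) < 0.75
  len <- integer(n_iso)
  len[is_coding] <- pmax(200L, as.integer(stats::rlnorm(sum(is_coding), log(2000), 0.6)))
  nc <- !is_coding
  small <- nc & stats::runif(n_iso) < 0.25
  len[nc & !small] <- pmax(201L, as.integer(stats::rlnorm(sum(nc & !small), log(1200), 0.7)))
  len[small] <- as.integer(stats::runif(sum(small), 20, 200))
  ann <- data.frame(isoform_id = iso_ids, gene_id = iso_gene,
                    is_coding = is_coding, length_nt = len,
                    stringsAsFactors = FALSE)

  x <- cbind(disc$x, vali$x)
  validate_expression(x)
  list(expression = x,
       samples = rbind(disc$samples, vali$samples),
       annotation = ann,
       truth = truth,
       config = cfg)
}
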