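# Synthetic cohort generator. Emulates the statistical structure of a
# case-control 16S study: a few hundred ASVs with log-normal baseline
# abundances and Dirichlet-multinomial counts, a hierarchical taxonomy, a
# random rooted phylogeny, and metadata (group, age, sex, BMI, macronutrient
# intakes) whose distributions follow the cohort's printed summary table.
# Group effects are planted as log-scale shifts on chosen taxa; optionally
# the informative taxa differ between samples above/below a carbohydrate
# threshold, so a nutrient-partitioned two-stage classifier has a genuine
# advantage over a single model.

#' Configuration for the synthetic cohort generator
#'
#' Defaults reproduce the study conditions the pipeline was designed around:
#' 103 PD cases vs 81 household controls, 627 ASVs (the size of the filtered
#' real-cohort table), mean sequencing depth 30,000 reads with log-normal
#' depth variation, and macronutrient intakes drawn from log-normal
#' distributions matched to the cohort's printed group means and SDs. The
#' planted carbohydrate stratum boundary defaults to 163.07 g/day, the
#' carbohydrate splitting node the study reports.
#'
#' @param n_group_a Number of PD samples.
#' @param n_group_b Number of HC samples.
#' @param n_asv Number of ASVs.
#' @param sequencing_depth_mean Mean reads per sample.
#' @param depth_dispersion SD of log depth (log-normal depth model).
#' @param n_differential Number of planted group-differential taxa (per
#'   stratum when `stratum_effect` is set).
#' @param effect_log2 Planted log2 fold change applied to differential taxa
#'   in the PD group.
#' @param nutrient_threshold Stratum boundary (g/day) on the nutrient named
#'   by `nutrient_var`.
#' @param stratum_effect If `TRUE`, two disjoint differential taxa sets are
#'   planted, one informative below the nutrient threshold and one above,
#'   and group membership is coupled to the stratum so the boundary is
#'   identifiable from the labels.
#' @param nutrient_var Metadata column carrying the stratum variable.
#' @param stratum_coupling Length-2 vector `c(p_low_pd, p_low_hc)`: the
#'   probability that a PD (resp. HC) sample falls in the low-nutrient
#'   stratum when `stratum_effect` is set. The default moderate coupling
#'   leaves both classes represented in each stratum (the regime that
#'   exercises the two-stage classifier); values near 0/1 give an almost
#'   label-pure boundary (the regime in which the planted threshold is
#'   recoverable to one grid step).
#' @param concentration Dirichlet concentration controlling per-sample
#'   overdispersion around the baseline composition: a taxon holding share
#'   q of the community has pseudo-count `concentration * q`, and taxa with
#'   pseudo-count above ~2 vary about 0.5-1 log2 unit between samples, the
#'   dispersion typical of detectable taxa in stool profiles.
#' @param baseline_sdlog SD of log baseline relative abundances.
#' @param male_rate_a,male_rate_b Bernoulli male rate per group (balanced by
#'   default; set to c(0.563, 0.321) to mirror the cohort's sex imbalance).
#' @param seed Integer seed; identical config + seed gives bit-identical
#'   cohorts.
#' @return A validated list of class `cohort_config`.
#' @export
cohort_config <- function(n_group_a = 103L, n_group_b = 81L, n_asv = 627L,
                          sequencing_depth_mean = 30000L,
                          depth_dispersion = 0.3,
                          n_differential = 10L, effect_log2 = 2,
                          nutrient_threshold = 163.07,
                          stratum_effect = FALSE,
                          nutrient_var = "carbohydrate_g",
                          stratum_coupling = c(0.15, 0.85),
                          concentration = 200,
                          baseline_sdlog = 2,
                          male_rate_a = 0.5, male_rate_b = 0.5,
                          seed = 1L) {
  cfg <- list(n_group_a = as.integer(n_group_a), n_group_b = as.integer(n_group_b),
              n_asv = as.integer(n_asv),
              sequencing_depth_mean = as.numeric(sequencing_depth_mean),
              depth_dispersion = depth_dispersion,
              n_differential = as.integer(n_differential),
              effect_log2 = effect_log2,
              nutrient_threshold = nutrient_threshold,
              stratum_effect = isTRUE(stratum_effect),
              nutrient_var = nutrient_var,
              stratum_coupling = as.numeric(stratum_coupling),
              concentration = concentration, baseline_sdlog = baseline_sdlog,
              male_rate_a = male_rate_a, male_rate_b = male_rate_b,
              seed = as.integer(seed))
  if (cfg$n_group_a < 0 || cfg$n_group_b < 0 || cfg$n_group_a + cfg$n_group_b < 1)
    stop("need at least one sample")
  if (cfg$n_asv < 2) stop("n_asv must be >= 2")
  if (cfg$sequencing_depth_mean <= 0) stop("sequencing_depth_mean must be positive")
  if (cfg$depth_dispersion <= 0) stop("depth_dispersion must be positive")
  if (cfg$n_differential > cfg$n_asv)
    stop("n_differential exceeds n_asv")
  if (cfg$stratum_effect && 2L * cfg$n_differential > cfg$n_asv)
    stop("stratum_effect needs two disjoint differential sets: 2*n_differential <= n_asv")
  if (cfg$concentration <= 0) stop("concentration must be positive")
  if (length(cfg$stratum_coupling) != 2 ||
      any(cfg$stratum_coupling < 0 | cfg$stratum_coupling > 1))
    stop("stratum_coupling must be two probabilities")
  class(cfg) <- "cohort_config"
  cfg
}

# Macronutrient intake distributions: printed group means/SDs of the cohort
# (g/day except energy in kJ/day), used as moments of log-normal laws.
.nutrient_moments <- list(
  protein_g      = list(a = c(118.4, 79.3),  b = c(116.7, 74.5)),
  fat_g          = list(a = c(101.7, 49.7),  b = c(95.7, 43.6)),
  carbohydrate_g = list(a = c(278.8, 161.8), b = c(232.2, 124.8)),
  sugar_g        = list(a = c(153.3, 86.3),  b = c(118.7, 60.6)),
  fiber_g        = list(a = c(41.1, 31.2),   b = c(38.1, 22.7))
)

# log-normal parameters matching a target mean and SD (vectorized)
.lnorm_par <- function(m, s) {
  sdlog <- sqrt(log(1 + (s / m)^2))
  list(meanlog = log(m) - sdlog^2 / 2, sdlog = sdlog)
}

.rlnorm_ms <- function(n, m, s) {
  p <- .lnorm_par(m, s)
  stats::rlnorm(n, p$meanlog, p$sdlog)
}

# log-normal draw truncated to (lo, hi) by inverse-CDF sampling
.rlnorm_trunc <- function(n, m, s, lo = 0, hi = Inf) {
  p <- .lnorm_par(m, s)
  u <- stats::runif(n, stats::plnorm(lo, p$meanlog, p$sdlog),
                    stats::plnorm(hi, p$meanlog, p$sdlog))
  stats::qlnorm(u, p$meanlog, p$sdlog)
}

#' Generate a random rooted phylogeny over ASV IDs
#'
#' Random binary rooted topology with uniform positive branch lengths,
#' serializable to Newick without loss.
#'
#' @param asv_ids Character vector of >= 2 leaf labels.
#' @param seed Integer seed.
#' @return An [ape::rtree()]-style `phylo` object with `asv_ids` as tips.
#' @export
generate_tree <- function(asv_ids, seed = 1L) {
  if (length(asv_ids) < 2) stop("need >= 2 leaves")
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(as.integer(seed))
  tree <- ape::rtree(length(asv_ids), rooted = TRUE, tip.label = asv_ids,
                     br = function(n) stats::runif(n, 0.05, 1))
  tree
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}
.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old, envir = globalenv())
}

# Random hierarchical taxonomy: each rank has fewer groups than the one
# below, scaled from the real cohort's 9 phyla / 31 orders / 48 families /
# 138 genera at 627 ASVs.
.generate_taxonomy <- function(asv_ids) {
  n <- length(asv_ids)
  n_gen <- max(2L, round(n * 138 / 627))
  n_fam <- max(2L, min(n_gen, round(n * 48 / 627)))
  n_ord <- max(2L, min(n_fam, round(n * 31 / 627)))
  n_phy <- max(2L, min(n_ord, round(n * 9 / 627)))
  gen_of_asv <- sample.int(n_gen, n, replace = TRUE)
  fam_of_gen <- sample.int(n_fam, n_gen, replace = TRUE)
  ord_of_fam <- sample.int(n_ord, n_fam, replace = TRUE)
  phy_of_ord <- sample.int(n_phy, n_ord, replace = TRUE)
  g <- gen_of_asv; f <- fam_of_gen[g]; o <- ord_of_fam[f]; p <- phy_of_ord[o]
  df <- data.frame(asv_id = asv_ids,
                   phylum = sprintf("Phylum_%02d", p),
                   order  = sprintf("Order_%02d", o),
                   family = sprintf("Family_%02d", f),
                   genus  = sprintf("Genus_%03d", g),
                   stringsAsFactors = FALSE)
  class(df) <- c("taxonomy_map", "data.frame")
  df
}

#' Generate a synthetic case-control cohort
#'
#' Draws, in documented order from a single seeded stream: baseline log-normal
#' ASV abundances, taxonomy, group labels and per-group demographics,
#' macronutrient intakes, nutrient strata (if `stratum_effect`), planted
#' differential taxa, and finally Dirichlet-multinomial counts. The
#' phylogeny uses a derived seed (`seed + 1`).
#'
#' Planted differential taxa are drawn from the upper half of baseline
#' abundance so that, like the detectable taxa of a real filtered ASV table,
#' they are observed in most samples.
#'
#' With `stratum_effect`, carbohydrate intake is drawn truncated to either
#' side of the threshold (with a 2% relative gap), stratum membership is
#' coupled to the group label (P(low stratum) = 0.25 for PD, 0.70 for HC,
#' so PD skews high-carbohydrate as in the cohort), and a disjoint taxa set
#' carries the group effect in each stratum.
#'
#' @param config A [cohort_config()].
#' @return A list of class `synthetic_cohort` with elements `counts`
#'   ([feature_table()]), `taxonomy`, `tree`, `metadata`, and `truth`
#'   (planted differential ASV IDs per stratum, threshold and nutrient).
#' @export
generate_cohort <- function(config = cohort_config()) {
  stopifnot(inherits(config, "cohort_config"))
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(config$seed)

  n_a <- config$n_group_a; n_b <- config$n_group_b; n <- n_a + n_b
  n_asv <- config$n_asv
  asv_ids <- sprintf("ASV_%04d", seq_len(n_asv))
  sample_ids <- sprintf("S%03d", seq_len(n))
  group <- c(rep("PD", n_a), rep("HC", n_b))

  # 1. baseline composition
  base_log <- stats::rnorm(n_asv, 0, config$baseline_sdlog)

  # 2. taxonomy
  tax <- .generate_taxonomy(asv_ids)

  # 3. demographics (cohort-matched normals, floors at plausible minima)
  age <- pmax(18, stats::rnorm(n, ifelse(group == "PD", 67.1, 62.4),
                               ifelse(group == "PD", 12.2, 15.6)))
  sex <- ifelse(stats::runif(n) < ifelse(group == "PD", config$male_rate_a,
                                         config$male_rate_b), "M", "F")
  bmi <- pmax(15, stats::rnorm(n, ifelse(group == "PD", 25.7, 26.2),
                               ifelse(group == "PD", 5.2, 4.6)))

  # 4. macronutrients
  nut <- lapply(names(.nutrient_moments), function(v) {
    mo <- .nutrient_moments[[v]]
    ifelse(group == "PD",
           .rlnorm_ms(n, mo$a[1], mo$a[2]),
           .rlnorm_ms(n, mo$b[1], mo$b[2]))
  })
  names(nut) <- names(.nutrient_moments)

  # 5. strata
  if (config$stratum_effect) {
    p_low <- ifelse(group == "PD", config$stratum_coupling[1],
                    config$stratum_coupling[2])
    stratum <- ifelse(stats::runif(n) < p_low, "low", "high")
    thr <- config$nutrient_threshold
    gap <- 0.02 * thr
    mo <- .nutrient_moments$carbohydrate_g
    m <- ifelse(group == "PD", mo$a[1], mo$b[1])
    s <- ifelse(group == "PD", mo$a[2], mo$b[2])
    carb <- numeric(n)
    lo_idx <- stratum == "low"
    carb[lo_idx] <- .rlnorm_trunc(sum(lo_idx), m[lo_idx], s[lo_idx],
                                  lo = 0, hi = thr - gap)
    carb[!lo_idx] <- .rlnorm_trunc(sum(!lo_idx), m[!lo_idx], s[!lo_idx],
                                   lo = thr + gap, hi = Inf)
    nut$carbohydrate_g <- carb
  } else {
    stratum <- rep("all", n)
  }

  # 6. energy and %-energy (Atwater-style factors: 16.7 kJ/g protein and
  #    carbohydrate, 37.7 kJ/g fat, plus a small residual intake term)
  energy <- 16.7 * (nut$protein_g + nut$carbohydrate_g) + 37.7 * nut$fat_g +
    .rlnorm_ms(n, 500, 250)
  pct_protein <- 100 * 16.7 * nut$protein_g / energy
  pct_fat <- 100 * 37.7 * nut$fat_g / energy
  pct_carbohydrate <- 100 * 16.7 * nut$carbohydrate_g / energy

  # 7. planted differential taxa, drawn from the well-measured pool: taxa
  #    whose Dirichlet pseudo-count (concentration x baseline share) is >= 2,
  #    where the log composition is close to normal and a planted CLR shift
  #    survives the compositional noise; fall back to the most abundant taxa
  #    if the pool is smaller than the number of sets to plant
  n_need <- if (config$stratum_effect) 2L * config$n_differential
            else config$n_differential
  base_share <- exp(base_log) / sum(exp(base_log))
  detectable <- which(config$concentration * base_share >= 2)
  if (length(detectable) < n_need)
    detectable <- order(base_log, decreasing = TRUE)[seq_len(n_need)]
  if (config$stratum_effect) {
    pick <- sample(detectable, 2L * config$n_differential)
    diff_low <- sort(pick[seq_len(config$n_differential)])
    diff_high <- sort(pick[config$n_differential + seq_len(config$n_differential)])
    truth_sets <- list(low = asv_ids[diff_low], high = asv_ids[diff_high])
  } else {
    diff_all <- sort(sample(detectable, config$n_differential))
    truth_sets <- list(all = asv_ids[diff_all])
  }

  # 8. counts: Dirichlet-multinomial around the (possibly shifted) baseline
  depth <- pmax(500, round(stats::rlnorm(
    n, log(config$sequencing_depth_mean) - config$depth_dispersion^2 / 2,
    config$depth_dispersion)))
  counts <- matrix(0, n_asv, n, dimnames = list(asv_ids, sample_ids))
  base_rel <- exp(base_log)
  alpha <- config$concentration * base_rel / sum(base_rel)
  for (i in seq_len(n)) {
    p <- stats::rgamma(n_asv, shape = alpha, rate = 1)
    p <- p / sum(p)
    # the group effect multiplies the realized composition, so the planted
    # log2 shift is carried at full strength by every planted taxon
    if (group[i] == "PD") {
      set <- if (config$stratum_effect) {
        if (stratum[i] == "low") diff_low else diff_high
      } else diff_all
      p[set] <- p[set] * 2^config$effect_log2
      p <- p / sum(p)
    }
    counts[, i] <- stats::rmultinom(1, depth[i], p)
  }

  metadata <- data.frame(
    sample_id = sample_ids, group = group, age = round(age, 1), sex = sex,
    bmi = round(bmi, 1),
    protein_g = round(nut$protein_g, 2), fat_g = round(nut$fat_g, 2),
    sugar_g = round(nut$sugar_g, 2), fiber_g = round(nut$fiber_g, 2),
    carbohydrate_g = round(nut$carbohydrate_g, 2),
    energy_kj = round(energy, 1),
    pct_protein = round(pct_protein, 2), pct_fat = round(pct_fat, 2),
    pct_carbohydrate = round(pct_carbohydrate, 2),
    stringsAsFactors = FALSE)

  tree <- if (n_asv >= 2) generate_tree(asv_ids, seed = config$seed + 1L) else NULL

  structure(list(
    counts = feature_table(counts, rank = "asv"),
    taxonomy = tax,
    tree = tree,
    metadata = metadata,
    truth = list(differential = truth_sets,
                 nutrient_var = config$nutrient_var,
                 nutrient_threshold = config$nutrient_threshold,
                 stratum = stats::setNames(stratum, sample_ids),
                 effect_log2 = config$effect_log2)),
    class = "synthetic_cohort")
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat(sprintf("synthetic_cohort: %d ASVs x %d samples (%d PD / %d HC)\n",
              nrow(x$counts$counts), ncol(x$counts$counts),
              sum(x$metadata$group == "PD"), sum(x$metadata$group == "HC")))
  invisible(x)
}

#' Write a synthetic cohort to a directory
#'
#' Writes `counts.tsv`, `taxonomy.tsv`, `metadata.tsv`, `tree.nwk` and
#' `truth.json` under `dir`.
#'
#' @param cohort A [generate_cohort()] result.
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "synthetic_cohort"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_counts(cohort$counts, file.path(dir, "counts.tsv"))
  write_taxonomy(cohort$taxonomy, file.path(dir, "taxonomy.tsv"))
  write_metadata(cohort$metadata, file.path(dir, "metadata.tsv"))
  if (!is.null(cohort$tree))
    ape::write.tree(cohort$tree, file.path(dir, "tree.nwk"))
  jsonlite::write_json(cohort$truth[c("differential", "nutrient_var",
                                      "nutrient_threshold", "effect_log2")],
                       file.path(dir, "truth.json"), auto_unbox = TRUE)
  invisible(dir)
}
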