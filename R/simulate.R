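#' Simulation configuration for a synthetic arrayed screen
#'
#' Collects the generative parameters of the synthetic screen. The defaults
#' are the study conditions the pipeline is designed for: a 96-well plate
#' with PBS-filled outer wells and duplicated scrambled-siRNA (negative),
#' PPARG-siRNA (positive) and transfection-reagent-only controls; lipid
#' signal linearly coupled to the DNA (cell-number) signal with slope
#' `k_true`; per-plate multiplicative and additive effects emulating
#' transfection-efficiency drift; per-siRNA knock-down efficacy drawn from a
#' Beta distribution; and planted hit genes of both signs acting
#' multiplicatively on lipid per cell.
#'
#' The default control scatter (`ctrl_cv = 0.07` together with
#' `dna_cv = 0.05` and the plate effect defaults) puts the analytic
#' Z'-factor of the corrected control distributions at approximately 0.42,
#' the screen-quality regime this assay operates in (the accounting includes
#' the residual the single-slope correction leaves on positive-control
#' wells, whose lipid-per-DNA slope is reduced by the knock-down).
#' `neg_mean` defaults to `k_true * dna_mean` so untargeted sample wells sit
#' at the negative-control level, and `pos_mean` to 40% of it (strong lipid
#' reduction when the master regulator of adipogenesis is silenced).
#'
#' @param seed Integer seed; all draws flow from this single generator.
#' @param n_genes Number of library genes (3 siRNAs each).
#' @param frac_hits_down,frac_hits_up Proportions of genes planted as
#'   lipid-reducing / lipid-increasing hits.
#' @param effect_size_down,effect_size_up Multiplicative lipid-per-cell
#'   effects at full knock-down (negative / positive).
#' @param efficacy_shape1,efficacy_shape2 Beta parameters of the per-siRNA
#'   knock-down efficacy in \[0, 1\].
#' @param k_true Lipid-versus-DNA coupling slope (AU lipid per AU DNA).
#' @param intercept Intercept of the lipid-DNA coupling (AU).
#' @param dna_mean,dna_cv Mean and coefficient of variation of the lognormal
#'   DNA (cell-number) signal.
#' @param dna_sample_factor Multiplier on `dna_mean` for sample wells only;
#'   values below 1 emulate screen-wide cell-number confounding (library
#'   transfection slightly reducing proliferation relative to controls).
#' @param plate_factor_sd SD of the multiplicative per-plate signal factor
#'   (centred at 1).
#' @param plate_offset_sd SD of the additive per-plate offset (AU).
#' @param meas_cv Multiplicative measurement noise CV for sample wells.
#' @param neg_mean,pos_mean Mean lipid level of negative / positive control
#'   wells at the reference cell number (AU).
#' @param ctrl_cv Multiplicative scatter CV of control wells.
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       n_genes = 200L,
                       frac_hits_down = 0,
                       frac_hits_up = 0,
                       effect_size_down = -0.6,
                       effect_size_up = 0.6,
                       efficacy_shape1 = 8,
                       efficacy_shape2 = 2,
                       k_true = 1.7181,
                       intercept = 0,
                       dna_mean = 100,
                       dna_cv = 0.05,
                       dna_sample_factor = 1,
                       plate_factor_sd = 0.02,
                       plate_offset_sd = 2,
                       meas_cv = 0.1,
                       neg_mean = k_true * dna_mean + intercept,
                       pos_mean = 0.4 * neg_mean,
                       ctrl_cv = 0.07) {
  cfg <- list(seed = as.integer(seed), n_genes = as.integer(n_genes),
              frac_hits_down = frac_hits_down, frac_hits_up = frac_hits_up,
              effect_size_down = effect_size_down,
              effect_size_up = effect_size_up,
              efficacy_shape1 = efficacy_shape1,
              efficacy_shape2 = efficacy_shape2,
              k_true = k_true, intercept = intercept,
              dna_mean = dna_mean, dna_cv = dna_cv,
              dna_sample_factor = dna_sample_factor,
              plate_factor_sd = plate_factor_sd,
              plate_offset_sd = plate_offset_sd,
              meas_cv = meas_cv, neg_mean = neg_mean, pos_mean = pos_mean,
              ctrl_cv = ctrl_cv)
  stopifnot(cfg$n_genes >= 1,
            cfg$frac_hits_down >= 0, cfg$frac_hits_up >= 0,
            cfg$frac_hits_down + cfg$frac_hits_up <= 1,
            cfg$k_true > 0, cfg$dna_mean > 0,
            cfg$dna_cv >= 0, cfg$meas_cv >= 0, cfg$ctrl_cv >= 0,
            cfg$plate_factor_sd >= 0, cfg$plate_offset_sd >= 0,
            cfg$efficacy_shape1 > 0, cfg$efficacy_shape2 > 0,
            cfg$effect_size_down <= 0, cfg$effect_size_up >= 0,
            cfg$dna_sample_factor > 0)
  class(cfg) <- "sim_config"
  cfg
}

# Lognormal draws parameterised by arithmetic mean and CV.
rlnorm_mean_cv <- function(n, mean, cv) {
  if (cv == 0) return(rep(mean, n))
  sdlog <- sqrt(log(1 + cv^2))
  stats::rlnorm(n, meanlog = log(mean) - sdlog^2 / 2, sdlog = sdlog)
}

#' Simulate a lipid-versus-DNA calibration experiment
#'
#' Generates paired (DNA, lipid) readouts on a dilution design: eight cell
#' densities spanning `dna_range`, replicated to `n_points` measurements
#' (default 48, i.e. six independent experiments of eight points), with
#' lipid linearly coupled to DNA at slope `k_true` plus multiplicative
#' measurement noise. The fitted slope of this design is the lipid data
#' correction factor.
#'
#' @param k_true True coupling slope (AU lipid per AU DNA).
#' @param n_points Number of paired measurements (>= 3).
#' @param noise_cv Measurement noise CV (relative to the mean lipid level).
#' @param seed Integer seed.
#' @param intercept True intercept (AU).
#' @param dna_range Range of DNA signals covered by the dilution series.
#' @return Data frame with columns `dna` and `lipid`.
#' @export
simulate_calibration <- function(k_true, n_points = 48L, noise_cv = 0.03,
                                 seed = 1L, intercept = 0,
                                 dna_range = c(25, 200)) {
  if (n_points < 3) {
    stop("n_points must be >= 3: regression undefined below that")
  }
  set.seed(seed)
  dna <- rep(seq(dna_range[1], dna_range[2], length.out = 8),
             length.out = n_points)
  dna <- sort(dna)
  mu <- k_true * dna + intercept
  lipid <- mu + stats::rnorm(n_points, 0, noise_cv * mean(mu))
  data.frame(dna = dna, lipid = lipid)
}

#' Simulate a paired cell-count / DNA-signal calibration
#'
#' Companion to [simulate_calibration()]: generates counted cells against
#' the Hoechst DNA signal used as a cell-number proxy, linear with
#' multiplicative noise.
#'
#' @param slope AU DNA per cell.
#' @param n_points Number of paired measurements.
#' @param noise_cv Noise CV on the DNA signal.
#' @param seed Integer seed.
#' @param cell_range Range of seeded cell counts.
#' @return Data frame with columns `cells` and `dna`.
#' @export
simulate_cell_proxy <- function(slope = 0.012, n_points = 48L,
                                noise_cv = 0.05, seed = 1L,
                                cell_range = c(2000, 16000)) {
  if (n_points < 3) stop("n_points must be >= 3")
  set.seed(seed)
  cells <- rep(seq(cell_range[1], cell_range[2], length.out = 8),
               length.out = n_points)
  cells <- sort(cells)
  mu <- slope * cells
  dna <- mu + stats::rnorm(n_points, 0, noise_cv * mean(mu))
  data.frame(cells = cells, dna = dna)
}

#' Simulate an arrayed siRNA screen with planted ground truth
#'
#' Generates a full multi-plate screen in the default 96-well layout. Genes
#' are assigned to classes (`null`, `hit_down`, `hit_up`) according to the
#' configured proportions; each siRNA draws a knock-down efficacy
#' `e ~ Beta(a, b)`; the lipid signal of a sample well is
#' `(k_true * D + intercept) * (1 + beta_g * e) * plate_factor *
#' (1 + meas_noise) + plate_offset`, with `D` lognormal. Control wells
#' couple to their own DNA draw the same way, scaled to the configured
#' control level, with control scatter `ctrl_cv`. The three siRNAs of a gene
#' are arrayed on three separate replicate plate sets, as vendor libraries
#' ship them, so a gene's per-siRNA scores share no plate.
#'
#' @param cfg A [sim_config()] object.
#' @param gene_classes Optional data frame with columns `gene_id` and
#'   `class` (`null`/`hit_down`/`hit_up`) prescribing the genes and their
#'   planted classes — used to re-screen the hits of a primary screen with
#'   a validation library; overrides `cfg$n_genes` and the hit fractions.
#' @param phase Library phase; `"validation"` draws new siRNA sequences for
#'   the same genes.
#' @return A list with elements `wells` (well table as from
#'   [load_plate_table()]), `truth` (list with `genes`: gene_id/class/beta,
#'   `sirnas`: sirna_id/gene_id/efficacy, and `k_true`) and `library` (the
#'   annotation table).
#' @export
simulate_screen <- function(cfg, gene_classes = NULL,
                            phase = c("primary", "validation")) {
  stopifnot(inherits(cfg, "sim_config"))
  phase <- match.arg(phase)
  set.seed(cfg$seed)
  if (is.null(gene_classes)) {
    n_genes <- cfg$n_genes
    lib <- make_library(n_genes, phase = phase)
    gene_ids <- unique(lib$gene_id)
    n_down <- round(cfg$frac_hits_down * n_genes)
    n_up <- round(cfg$frac_hits_up * n_genes)
    classes <- rep("null", n_genes)
    shuffled <- sample.int(n_genes)
    if (n_down > 0) classes[shuffled[seq_len(n_down)]] <- "hit_down"
    if (n_up > 0) classes[shuffled[n_down + seq_len(n_up)]] <- "hit_up"
  } else {
    stopifnot(all(c("gene_id", "class") %in% names(gene_classes)),
              all(gene_classes$class %in% c("null", "hit_down", "hit_up")))
    n_genes <- nrow(gene_classes)
    gene_ids <- gene_classes$gene_id
    lib <- make_library(n_genes, phase = phase, gene_ids = gene_ids)
    classes <- gene_classes$class
  }
  cfg$n_genes <- n_genes
  beta <- ifelse(classes == "hit_down", cfg$effect_size_down,
          ifelse(classes == "hit_up", cfg$effect_size_up, 0))
  genes <- data.frame(gene_id = gene_ids, class = classes, beta = beta,
                      stringsAsFactors = FALSE)

  efficacy <- stats::rbeta(nrow(lib), cfg$efficacy_shape1,
                           cfg$efficacy_shape2)
  sirnas <- data.frame(sirna_id = lib$sirna_id, gene_id = lib$gene_id,
                       efficacy = efficacy, stringsAsFactors = FALSE)

  layout <- build_default_layout()
  sample_pos <- layout[layout$role == "sample", ]
  n_per_plate <- nrow(sample_pos)  # 54

  plates_per_set <- ceiling(cfg$n_genes / n_per_plate)
  well_list <- vector("list", 3 * plates_per_set)
  pi <- 0
  for (r in 1:3) {
    rep_sirnas <- sirnas[seq(r, nrow(sirnas), by = 3), ]  # siRNA r of each gene
    for (p in seq_len(plates_per_set)) {
      idx <- ((p - 1) * n_per_plate + 1):min(p * n_per_plate, cfg$n_genes)
      plate_id <- sprintf("S%dP%02d", r, p)
      plate <- layout
      plate$plate_id <- plate_id
      plate$sirna_id <- NA_character_
      plate$gene_id <- NA_character_
      filled <- seq_along(idx)
      srows <- which(plate$role == "sample")[filled]
      plate$sirna_id[srows] <- rep_sirnas$sirna_id[idx]
      plate$gene_id[srows] <- rep_sirnas$gene_id[idx]
      # unfilled sample wells on the last plate carry no reagent
      unfilled <- setdiff(which(plate$role == "sample"), srows)
      if (length(unfilled) > 0) plate$role[unfilled] <- "edge_excluded"
      pi <- pi + 1
      well_list[[pi]] <- plate
    }
  }
  wells <- do.call(rbind, well_list)

  plate_ids <- unique(wells$plate_id)
  pf <- 1 + stats::rnorm(length(plate_ids), 0, cfg$plate_factor_sd)
  po <- stats::rnorm(length(plate_ids), 0, cfg$plate_offset_sd)
  names(pf) <- names(po) <- plate_ids

  measured <- wells$role != "edge_excluded"
  n_meas <- sum(measured)
  dna_mean_w <- ifelse(wells$role[measured] == "sample",
                       cfg$dna_mean * cfg$dna_sample_factor, cfg$dna_mean)
  dna <- rlnorm_mean_cv(n_meas, 1, cfg$dna_cv) * dna_mean_w

  beta_w <- rep(0, n_meas)
  eff_w <- rep(1, n_meas)
  is_sample <- wells$role[measured] == "sample"
  sid <- wells$sirna_id[measured][is_sample]
  eff_w[is_sample] <- sirnas$efficacy[match(sid, sirnas$sirna_id)]
  beta_w[is_sample] <- genes$beta[match(sirnas$gene_id[
    match(sid, sirnas$sirna_id)], genes$gene_id)]
  # control level multipliers relative to the untargeted lipid level
  role_m <- wells$role[measured]
  level <- rep(1, n_meas)
  level[role_m == "pos_control"] <- cfg$pos_mean / cfg$neg_mean
  noise_cv_w <- ifelse(role_m == "sample", cfg$meas_cv, cfg$ctrl_cv)

  base <- (cfg$k_true * dna + cfg$intercept) * level * (1 + beta_w * eff_w)
  lipid <- base * pf[wells$plate_id[measured]] *
    (1 + stats::rnorm(n_meas, 0, noise_cv_w)) + po[wells$plate_id[measured]]

  wells$lipid_raw <- NA_real_
  wells$dna_raw <- NA_real_
  wells$lipid_raw[measured] <- lipid
  wells$dna_raw[measured] <- dna
  wells$lipid_corrected <- NA_real_
  wells$qc_flag <- ifelse(wells$role == "edge_excluded", "excluded", "ok")
  wells <- wells[, c("plate_id", "row", "col", "role", "sirna_id", "gene_id",
                     "lipid_raw", "dna_raw", "lipid_corrected", "qc_flag")]
  rownames(wells) <- NULL

  list(wells = wells,
       truth = list(genes = genes, sirnas = sirnas, k_true = cfg$k_true),
       library = lib)
}

#' Simulate an In-Cell Western marker table with planted phenotype classes
#'
#' Emulates the two-marker (aP2, Perilipin A) immunofluorescence readout
#' normalized to GAPDH. Genes planted as `reduced_differentiation` shift
#' both markers down by `effect_pct`, `increased_differentiation` shifts
#' both up, and `no_change` (lipid-turnover) genes leave both markers within
#' noise. Scrambled-siRNA control wells (gene id `"scrambled"`) are included
#' for normalization.
#'
#' @param classes Data frame with columns `gene_id` and `class`
#'   (`reduced_differentiation`, `increased_differentiation`, `no_change`).
#' @param seed Integer seed.
#' @param effect_pct Planted marker shift in percent of the control level.
#' @param noise_sd_pct Per-well noise SD in percent.
#' @param n_ctrl Number of scrambled control wells per marker.
#' @return Data frame with columns `gene_id`, `sirna_id`, `marker`
#'   (`aP2`/`PerilipinA`), `marker_signal`, `gapdh_signal`.
#' @export
simulate_icw <- function(classes, seed = 1L, effect_pct = 40,
                         noise_sd_pct = 3, n_ctrl = 6L) {
  stopifnot(all(c("gene_id", "class") %in% names(classes)))
  ok <- c("reduced_differentiation", "increased_differentiation", "no_change")
  bad <- setdiff(unique(classes$class), ok)
  if (length(bad) > 0) stop("unknown ICW class: ", paste(bad, collapse = ", "))
  set.seed(seed)
  shift <- ifelse(classes$class == "reduced_differentiation", -effect_pct,
           ifelse(classes$class == "increased_differentiation", effect_pct, 0))
  grid <- expand.grid(sirna = 1:3, marker = c("aP2", "PerilipinA"),
                      i = seq_len(nrow(classes)),
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  base_level <- c(aP2 = 1.2, PerilipinA = 0.8)  # marker-specific scale
  n <- nrow(grid)
  gapdh <- 50 * (1 + stats::rnorm(n, 0, 0.02))
  dev <- shift[grid$i] + stats::rnorm(n, 0, noise_sd_pct)
  records <- data.frame(
    gene_id = classes$gene_id[grid$i],
    sirna_id = paste0(classes$gene_id[grid$i], "_k", grid$sirna),
    marker = grid$marker,
    marker_signal = gapdh * base_level[grid$marker] * (1 + dev / 100),
    gapdh_signal = gapdh,
    stringsAsFactors = FALSE
  )
  cg <- expand.grid(sirna = seq_len(n_ctrl), marker = c("aP2", "PerilipinA"),
                    KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  nc <- nrow(cg)
  gapdh_c <- 50 * (1 + stats::rnorm(nc, 0, 0.02))
  dev_c <- stats::rnorm(nc, 0, noise_sd_pct)
  controls <- data.frame(
    gene_id = "scrambled",
    sirna_id = paste0("scr_", cg$sirna),
    marker = cg$marker,
    marker_signal = gapdh_c * base_level[cg$marker] * (1 + dev_c / 100),
    gapdh_signal = gapdh_c,
    stringsAsFactors = FALSE
  )
  rbind(records, controls)
}

#' Simulate a per-probe expression table with planted regulation
#'
#' Generates microarray-style signed fold changes and p-values for the
#' d0-vs-d3 and d0-vs-d7 comparisons. Genes planted as regulated receive one
#' probe passing the |FC| >= 2, p <= 0.01 rule in at least one comparison
#' with the planted sign; null genes stay below both cutoffs.
#'
#' @param truth Data frame with columns `gene_id` and `regulation`
#'   (`up`, `down`, `none`).
#' @param seed Integer seed.
#' @return Data frame with columns `gene_id`, `probe_id`, `comparison`,
#'   `fold_change`, `p_value` (signed-fold convention: no values in (-1, 1)).
#' @export
simulate_expression <- function(truth, seed = 1L) {
  stopifnot(all(c("gene_id", "regulation") %in% names(truth)))
  set.seed(seed)
  rows <- list()
  for (i in seq_len(nrow(truth))) {
    g <- truth$gene_id[i]
    reg <- truth$regulation[i]
    for (cmp in c("d0_vs_d3", "d0_vs_d7")) {
      if (reg != "none" && cmp == "d0_vs_d7") {
        fc <- stats::runif(1, 2.5, 30) * if (reg == "down") -1 else 1
        p <- 10^stats::runif(1, -20, -4)
      } else {
        fc <- stats::runif(1, 1.05, 1.8) * sample(c(-1, 1), 1)
        p <- stats::runif(1, 0.05, 0.9)
      }
      rows[[length(rows) + 1]] <- data.frame(
        gene_id = g, probe_id = paste0(g, "_p1"), comparison = cmp,
        fold_change = fc, p_value = p, stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}
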