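# Mechanism-structured synthetic pharmacogenomic panel generator.
#
# Drugs are grouped into mechanisms that share a fingerprint template and a
# cell-sensitivity slope; responses follow a linear latent-sensitivity model
# in which per-drug mean responses dominate total variance, mirroring the
# regime in which drug response models mostly learn per-drug response
# distributions.

#' Configure the synthetic panel generator
#'
#' The generative model: each mechanism `m` gets a fingerprint template with
#' i.i.d. Bernoulli(`p_on`) bits, a response mean `mu_m ~ N(0, sigma2_mech)`
#' and a sensitivity slope `beta_m ~ N(b0, sigma2_beta)`.  Drug `d` of
#' mechanism `m` copies the template with each bit flipped independently
#' with probability `flip_rate`, and adds a mean offset
#' `delta_d ~ N(0, sigma2_drug)` and slope offset
#' `gamma_d ~ N(0, sigma2_slope)`.  Cell `c` carries a latent sensitivity
#' vector `s_c ~ N(0, I_M)` observed only through noisy features
#' `x_c = L s_c + N(0, sigma2_feat I)` with loading entries `N(0, 1/M)`.
#' The measured response is
#' `y_cd = mu_m + delta_d + (beta_m + gamma_d) * s_cm + N(0, sigma2_noise)`.
#' A `confusable` mechanism pair copies the first member's template exactly
#' and negates its slope: structurally near-identical drugs with opposed
#' pharmacology.
#'
#' Defaults put roughly 69% of response variance on per-drug means
#' (`sigma2_mech + sigma2_drug`), 21% on the cell-by-drug interaction and
#' 9% on noise, the drug-mean-dominated regime of real screens.
#'
#' @param n_mechanisms number of mechanisms `M`.
#' @param drugs_per_mechanism drugs per mechanism.
#' @param n_cells number of cell lines.
#' @param n_cell_features observed cell feature dimension `G`.
#' @param fingerprint_width fingerprint length `F`.
#' @param p_on template bit density, in (0,1).
#' @param flip_rate per-bit template flip probability, in [0, 0.5).
#' @param sigma2_mech,sigma2_drug variances of mechanism means and drug
#'   mean offsets.
#' @param b0,sigma2_beta mean and variance of mechanism slopes.
#' @param sigma2_slope variance of per-drug slope offsets.
#' @param sigma2_noise residual response variance.
#' @param sigma2_feat cell feature noise variance.
#' @param confusable_pairs list of length-2 character vectors of mechanism
#'   labels (`"M1"` ... `"M<M>"`).
#' @param pairing_density fraction of cell-by-drug pairs measured, in (0,1].
#' @param seed integer seed; all generator randomness flows from it.
#' @return A [SimConfig-class].
#' @examples
#' simConfig(n_mechanisms = 2, drugs_per_mechanism = 3, n_cells = 20)
#' @export
simConfig <- function(n_mechanisms = 6, drugs_per_mechanism = 5,
                      n_cells = 150, n_cell_features = 200,
                      fingerprint_width = 256, p_on = 0.1, flip_rate = 0.05,
                      sigma2_mech = 1.0, sigma2_drug = 0.5, b0 = 0.6,
                      sigma2_beta = 0.05, sigma2_slope = 0.05,
                      sigma2_noise = 0.2, sigma2_feat = 0.05,
                      confusable_pairs = list(), pairing_density = 1.0,
                      seed = 1L) {
  new("SimConfig", n_mechanisms = as.integer(n_mechanisms),
      drugs_per_mechanism = as.integer(drugs_per_mechanism),
      n_cells = as.integer(n_cells),
      n_cell_features = as.integer(n_cell_features),
      fingerprint_width = as.integer(fingerprint_width),
      p_on = p_on, flip_rate = flip_rate, sigma2_mech = sigma2_mech,
      sigma2_drug = sigma2_drug, b0 = b0, sigma2_beta = sigma2_beta,
      sigma2_slope = sigma2_slope, sigma2_noise = sigma2_noise,
      sigma2_feat = sigma2_feat,
      confusable_pairs = lapply(confusable_pairs, as.character),
      pairing_density = pairing_density, seed = as.integer(seed))
}

.with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()))
  }
  set.seed(seed)
  expr
}

#' Generate a synthetic pharmacogenomic panel with known ground truth
#'
#' Draws one realization of the generative model described in
#' [simConfig()].  The annotation table labels each drug's putative target
#' with its mechanism and its pathway with a mechanism group (consecutive
#' mechanisms paired), so mechanism-aware stages can run unchanged on
#' synthetic data.
#'
#' @param config a [SimConfig-class].
#' @return list with elements `panel` ([ResponsePanel-class]), `drugs`
#'   ([DrugFeatureSet-class]), `cells` ([CellFeatureSet-class]),
#'   `annotations` ([AnnotationTable-class]) and `truth`
#'   ([SyntheticGroundTruth-class]).
#' @examples
#' sim <- generatePanel(simConfig(n_mechanisms = 2, drugs_per_mechanism = 2,
#'                                n_cells = 10, n_cell_features = 20,
#'                                fingerprint_width = 32))
#' sim$panel
#' @export
generatePanel <- function(config) {
  validObject(config)
  M <- config@n_mechanisms
  dpm <- config@drugs_per_mechanism
  nc <- config@n_cells
  G <- config@n_cell_features
  fw <- config@fingerprint_width
  mechs <- paste0("M", seq_len(M))
  drug_ids <- paste0("D", formatC(seq_len(M * dpm), width = 3, flag = "0"))
  mech_of <- setNames(rep(mechs, each = dpm), drug_ids)
  cells <- paste0("C", formatC(seq_len(nc), width = 3, flag = "0"))

  .with_seed(config@seed, {
    templates <- matrix(rbinom(M * fw, 1, config@p_on), nrow = M,
                        dimnames = list(mechs, NULL))
    mu <- setNames(rnorm(M, 0, sqrt(config@sigma2_mech)), mechs)
    beta <- setNames(rnorm(M, config@b0, sqrt(config@sigma2_beta)), mechs)
    for (p in config@confusable_pairs) {
      templates[p[2], ] <- templates[p[1], ]
      beta[p[2]] <- -beta[p[1]]
    }
    delta <- setNames(rnorm(length(drug_ids), 0, sqrt(config@sigma2_drug)),
                      drug_ids)
    gamma <- setNames(rnorm(length(drug_ids), 0, sqrt(config@sigma2_slope)),
                      drug_ids)

    flips <- matrix(rbinom(length(drug_ids) * fw, 1, config@flip_rate),
                    nrow = length(drug_ids))
    fingerprints <- abs(templates[mech_of, , drop = FALSE] - flips)
    rownames(fingerprints) <- drug_ids

    s <- matrix(rnorm(nc * M), nrow = nc, dimnames = list(cells, mechs))
    L <- matrix(rnorm(G * M, 0, sqrt(1 / M)), nrow = G)
    x <- s %*% t(L) + matrix(rnorm(nc * G, 0, sqrt(config@sigma2_feat)),
                             nrow = nc)
    rownames(x) <- cells
    colnames(x) <- paste0("G", formatC(seq_len(G), width = 4, flag = "0"))

    grid <- expand.grid(cell_id = cells, drug_id = drug_ids,
                        KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
    if (config@pairing_density < 1) {
      keep <- sample.int(nrow(grid),
                         max(1L, round(config@pairing_density * nrow(grid))))
      grid <- grid[sort(keep), , drop = FALSE]
    }
    m <- mech_of[grid$drug_id]
    sens <- s[cbind(grid$cell_id, m)]
    y <- mu[m] + delta[grid$drug_id] +
      (beta[m] + gamma[grid$drug_id]) * sens +
      rnorm(nrow(grid), 0, sqrt(config@sigma2_noise))
    grid$response <- as.numeric(y)
  })

  counts <- table(grid$drug_id)
  thin <- names(counts)[counts < 2]
  if (length(thin))
    warning("drugs measured on fewer than 2 cells: ",
            paste(thin, collapse = ", "))

  pathway_of <- setNames(paste0("P", (match(mech_of, mechs) + 1L) %/% 2L),
                         drug_ids)
  ann <- AnnotationTable(data.frame(drug_id = drug_ids,
                                    putative_target = unname(mech_of),
                                    pathway = unname(pathway_of)))
  truth <- new("SyntheticGroundTruth", mechanism = mech_of,
               templates = templates, mu = mu, delta = delta, beta = beta,
               gamma = gamma, sensitivities = s, loading = L,
               config = config)
  list(panel = ResponsePanel(grid, metric = "EC50"),
       drugs = DrugFeatureSet(fingerprints, mechanism = mech_of,
                              pathway = pathway_of),
       cells = CellFeatureSet(x, encoding = "expression"),
       annotations = ann, truth = truth)
}

#' Empirical variance decomposition of a synthetic panel
#'
#' Splits total response variance into the between-drug share (variance of
#' per-drug means), the cell-by-drug interaction share (the slope-times-
#' sensitivity term, computed from ground truth) and the residual share
#' (everything else, including the small empirical cross term), which sum
#' exactly to one.  Used to check that a panel sits in the intended
#' drug-mean-dominated regime.
#'
#' @param panel a [ResponsePanel-class] produced by [generatePanel()].
#' @param truth the matching [SyntheticGroundTruth-class].
#' @return data.frame with `component` and `share`.
#' @export
varianceReport <- function(panel, truth) {
  t <- panel@tuples
  m <- truth@mechanism[t$drug_id]
  g <- (truth@beta[m] + truth@gamma[t$drug_id]) *
    truth@sensitivities[cbind(t$cell_id, m)]
  y <- t$response
  ss_tot <- sum((y - mean(y))^2)
  drug_mean <- ave(y, t$drug_id)
  ss_between <- sum((drug_mean - mean(y))^2)
  g_centered <- g - ave(g, t$drug_id)
  ss_inter <- sum(g_centered^2)
  shares <- c(between_drug = ss_between / ss_tot,
              interaction = ss_inter / ss_tot)
  shares <- c(shares, residual = 1 - sum(shares))
  data.frame(component = names(shares), share = unname(shares))
}

#' Closed-form variance shares implied by a SimConfig
#'
#' @param config a [SimConfig-class].
#' @return named numeric: expected between-drug, interaction and noise
#'   shares of total response variance.
#' @export
expectedVarianceShares <- function(config) {
  between <- config@sigma2_mech + config@sigma2_drug
  inter <- config@b0^2 + config@sigma2_beta + config@sigma2_slope
  noise <- config@sigma2_noise
  tot <- between + inter + noise
  c(between_drug = between / tot, interaction = inter / tot,
    residual = noise / tot)
}

#' Write a synthetic panel to the delimited formats the readers consume
#'
#' Emits `response.csv`, `expression.csv`, `annotations.csv`,
#' `fingerprints.csv` and a `truth.json` holding all generator parameters
#' and assignments, so external tools (or the package's own readers) can
#' round-trip the data.
#'
#' @param sim result of [generatePanel()].
#' @param dir output directory (created if needed).
#' @return invisibly, the directory path.
#' @export
writeSyntheticData <- function(sim, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  t <- sim$panel@tuples
  write.csv(data.frame(cell_line = t$cell_id, drug = t$drug_id,
                       value = t$response),
            file.path(dir, "response.csv"), row.names = FALSE)
  x <- featureMatrix(sim$cells)
  write.csv(cbind(data.frame(cell_id = rownames(x)), as.data.frame(x)),
            file.path(dir, "expression.csv"), row.names = FALSE)
  write.csv(annotationRows(sim$annotations),
            file.path(dir, "annotations.csv"), row.names = FALSE)
  fp <- featureMatrix(sim$drugs)
  write.csv(cbind(data.frame(drug_id = rownames(fp)), as.data.frame(fp)),
            file.path(dir, "fingerprints.csv"), row.names = FALSE)
  cfg <- sim$truth@config
  truth <- list(
    config = list(n_mechanisms = cfg@n_mechanisms,
                  drugs_per_mechanism = cfg@drugs_per_mechanism,
                  n_cells = cfg@n_cells, n_cell_features = cfg@n_cell_features,
                  fingerprint_width = cfg@fingerprint_width, p_on = cfg@p_on,
                  flip_rate = cfg@flip_rate, sigma2_mech = cfg@sigma2_mech,
                  sigma2_drug = cfg@sigma2_drug, b0 = cfg@b0,
                  sigma2_beta = cfg@sigma2_beta,
                  sigma2_slope = cfg@sigma2_slope,
                  sigma2_noise = cfg@sigma2_noise,
                  sigma2_feat = cfg@sigma2_feat,
                  confusable_pairs = cfg@confusable_pairs,
                  pairing_density = cfg@pairing_density, seed = cfg@seed),
    mechanism = as.list(sim$truth@mechanism),
    mu = as.list(sim$truth@mu), delta = as.list(sim$truth@delta),
    beta = as.list(sim$truth@beta), gamma = as.list(sim$truth@gamma))
  jsonlite::write_json(truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
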