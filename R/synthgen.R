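# Seeded generator of synthetic ontologies, molecules, protocols, auxiliary
# ADMET tables and labelled trials from a planted outcome model.  Approval
# is Bernoulli in a logistic latent score that is linear in mean drug
# toxicity, max disease risk and a protocol-quality term, plus a per-phase
# offset calibrated so marginal success rates match published phase-level
# rates (56.3% / 49.8% / 67.8% for phases I/II/III), plus Gaussian noise
# whose scale is calibrated to a target Bayes-optimal AUC.

# ~50 hand-validated small-molecule SMILES; sampled with replacement so
# generation needs no chemistry dependency, while every string parses under
# the molecule reader.
SMILES_VOCAB <- c(
  "CCO", "CC(=O)O", "CC(=O)Oc1ccccc1C(=O)O", "CN1C=NC2=C1C(=O)N(C)C(=O)N2C",
  "CC(C)Cc1ccc(cc1)C(C)C(=O)O", "CC(=O)Nc1ccc(O)cc1", "c1ccccc1",
  "Cc1ccccc1", "Oc1ccccc1", "Nc1ccccc1", "OC(=O)c1ccccc1", "ClC(Cl)Cl",
  "CCN(CC)CC", "CC(N)C(=O)O", "NCC(=O)O", "OCC(O)CO", "C1CCCCC1",
  "C1CCNCC1", "c1ccncc1", "c1ccc2ccccc2c1", "CC(C)O", "CCOC(=O)C",
  "NC(=O)c1ccccc1", "COc1ccccc1", "CCCCCC", "OCCO", "CC(=O)C", "CSC",
  "OS(=O)(=O)c1ccccc1", "FC(F)(F)c1ccccc1", "Clc1ccccc1", "Brc1ccccc1",
  "Ic1ccccc1", "N#Cc1ccccc1", "O=[N+]([O-])c1ccccc1", "OCCN",
  "CCc1ccccc1", "CN(C)c1ccccc1", "O=Cc1ccccc1", "CC(=O)c1ccccc1",
  "OCc1ccccc1", "NCCc1ccccc1", "OC(=O)CCc1ccccc1", "c1ccc(cc1)-c1ccccc1",
  "Oc1ccc(O)cc1", "Nc1ccc(N)cc1", "OC(=O)c1ccc(O)cc1",
  "CC1=CC(=O)CC(C)(C)C1", "c1ccc2ncccc2c1", "CC(C)NCC(O)COc1ccccc1")

PHASES <- c("I", "II", "III")

# criteria sentence templates, keyed by protocol-quality tercile; the text
# carries the planted protocol signal (and the phase) so a text encoder can
# recover it
.protocol_templates <- list(
  low = c(
    "open label single arm study without control group",
    "inclusion adults with the condition no biomarker requirement",
    "exclusion none specified broad enrollment permitted",
    "endpoint unvalidated surrogate measure investigator assessed",
    "inclusion any prior therapy allowed unrestricted washout"),
  mid = c(
    "randomized controlled study with standard of care comparator",
    "inclusion adults aged 18 to 75 with confirmed diagnosis",
    "exclusion pregnant or breastfeeding participants",
    "endpoint clinical response at scheduled follow up visit",
    "exclusion severe renal or hepatic impairment"),
  high = c(
    "randomized double blind placebo controlled multicenter design",
    "inclusion biomarker stratified cohorts with central adjudication",
    "exclusion prior exposure to investigational agent strict washout",
    "endpoint validated primary outcome with blinded review committee",
    "inclusion adequate organ function documented screening labs"))

#' Configuration of the synthetic trial generator
#'
#' Defaults define the emulated study conditions: phase success rates match
#' published phase-level marginals (56.3/49.8/67.8%), the phase mix follows
#' the published phase counts, dates are uniform over a 6-year window with
#' the split date at its 60% quantile, and the noise scale is calibrated so
#' the Bayes-optimal classifier attains a target AUC of 0.85.
#'
#' @param n_trials Number of trials to generate.
#' @param phase_mix Fractions of trials in phases I/II/III (sum to 1).
#' @param phase_success_rates Marginal success probability per phase.
#' @param ontology_depth,branching Shape of the generated disease ontology.
#' @param n_molecules Size of the molecule vocabulary used (<= 50).
#' @param effect_sizes Coefficients of the planted linear model, named
#'   \code{toxicity}, \code{disease_risk}, \code{protocol}.
#' @param noise_sd Latent Gaussian noise SD; \code{NULL} (default) calibrates
#'   it to \code{bayes_auc_target}.
#' @param bayes_auc_target Target AUC of the Bayes-optimal classifier.
#' @param date_window Two dates bounding start dates.
#' @param split_date Temporal split date.
#' @param seed Integer seed; all generation is deterministic given it.
#' @return List of class \code{synth_config}.
#' @export
synth_config <- function(n_trials = 2000,
                         phase_mix = c(I = 0.143, II = 0.490, III = 0.367),
                         phase_success_rates = c(I = 0.563, II = 0.498, III = 0.678),
                         ontology_depth = 3, branching = 3,
                         n_molecules = 50,
                         effect_sizes = c(toxicity = 5, disease_risk = 4,
                                          protocol = 3),
                         noise_sd = NULL,
                         bayes_auc_target = 0.85,
                         date_window = c("2010-01-01", "2015-12-31"),
                         split_date = "2013-08-08",
                         seed = 1) {
  stopifnot(n_trials >= 1, length(phase_mix) == 3,
            abs(sum(phase_mix) - 1) < 1e-8,
            all(phase_success_rates > 0 & phase_success_rates < 1),
            n_molecules >= 1, n_molecules <= length(SMILES_VOCAB),
            all(c("toxicity", "disease_risk", "protocol") %in%
                  names(effect_sizes)))
  if (!is.null(bayes_auc_target))
    stopifnot(bayes_auc_target > 0.5, bayes_auc_target < 1)
  names(phase_mix) <- PHASES
  names(phase_success_rates) <- PHASES
  structure(list(
    n_trials = n_trials, phase_mix = phase_mix,
    phase_success_rates = phase_success_rates,
    ontology_depth = ontology_depth, branching = branching,
    n_molecules = n_molecules, effect_sizes = effect_sizes,
    noise_sd = noise_sd, bayes_auc_target = bayes_auc_target,
    date_window = as.Date(date_window), split_date = as.Date(split_date),
    seed = as.integer(seed)), class = "synth_config")
}

# conditional success probability given covariate signal s, integrating the
# latent Gaussian noise by a deterministic quantile rule
.noise_integrated_prob <- function(s, noise_sd, m = 101) {
  if (noise_sd <= 0) return(stats::plogis(s))
  z <- stats::qnorm((seq_len(m) - 0.5) / m) * noise_sd
  rowMeans(outer(s, z, function(a, b) stats::plogis(a + b)))
}

#' Generate labelled synthetic trials from the planted outcome model
#'
#' @param config A [synth_config()].
#' @return List with \code{trials} (data.frame, one row per trial:
#'   trial_id, smiles, icd_codes, criteria (JSON), phase, start_date,
#'   completion_date, label), \code{ontology}, and \code{truth}
#'   (\code{planted_truth}: per-trial latent score / Bayes probability,
#'   per-molecule attributes, per-disease risks, realized noise_sd and
#'   phase offsets).
#' @export
gen_trials <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  set.seed(config$seed)
  n <- config$n_trials
  onto <- gen_ontology(config$ontology_depth, config$branching,
                       seed = config$seed)
  leaves <- ontology_leaves(onto)
  mols <- SMILES_VOCAB[seq_len(config$n_molecules)]
  # planted per-molecule ADMET attributes (col T is the toxicity that drives
  # outcomes) and per-code disease risks
  attrs <- matrix(stats::runif(length(mols) * 5), ncol = 5,
                  dimnames = list(mols, c("A", "D", "M", "E", "T")))
  risk <- stats::setNames(stats::runif(length(onto$codes)), onto$codes)

  phase <- sample(PHASES, n, replace = TRUE, prob = config$phase_mix)
  drugs <- lapply(seq_len(n), function(i)
    sample(mols, sample(1:3, 1), replace = FALSE))
  dis <- lapply(seq_len(n), function(i)
    sample(leaves, sample(1:2, 1), replace = FALSE))
  quality <- stats::runif(n)
  qbucket <- cut(quality, c(-Inf, 1 / 3, 2 / 3, Inf),
                 labels = c("low", "mid", "high"))
  prot_score <- (as.integer(qbucket) - 2) / 2   # -0.5, 0, +0.5

  es <- config$effect_sizes
  signal <- es[["toxicity"]] * (0.5 - vapply(drugs, function(d)
      mean(attrs[d, "T"]), numeric(1))) +
    es[["disease_risk"]] * (0.5 - vapply(dis, function(d)
      max(risk[d]), numeric(1))) +
    es[["protocol"]] * prot_score

  noise_sd <- config$noise_sd
  if (is.null(noise_sd)) {
    target <- config$bayes_auc_target
    auc_at <- function(sd) {
      p <- .noise_integrated_prob(signal, sd)
      expected_auc_weighted(p)
    }
    lo <- 0; hi <- 10
    if (auc_at(0) < target)
      noise_sd <- 0        # signal alone cannot reach the target; no noise
    else {
      for (it in 1:40) {
        mid <- (lo + hi) / 2
        if (auc_at(mid) >= target) lo <- mid else hi <- mid
      }
      noise_sd <- (lo + hi) / 2
    }
  }

  # per-phase offsets matching marginal success rates given the drawn signals
  offsets <- stats::setNames(numeric(3), PHASES)
  for (ph in PHASES) {
    idx <- phase == ph
    rate <- config$phase_success_rates[[ph]]
    if (!any(idx)) next
    lim <- 20 + 5 * noise_sd     # the offset must outweigh the noise spread
    offsets[ph] <- stats::uniroot(function(o)
      mean(.noise_integrated_prob(signal[idx] + o, noise_sd)) - rate,
      c(-lim, lim), tol = 1e-10)$root
  }

  bayes_prob <- .noise_integrated_prob(signal + offsets[phase], noise_sd)
  label <- stats::rbinom(n, 1, bayes_prob)

  # criteria: first sentence names the phase, the rest are drawn from the
  # quality-matched template pool
  criteria <- vapply(seq_len(n), function(i) {
    k <- sample(2:6, 1)
    pool <- .protocol_templates[[as.character(qbucket[i])]]
    sent <- c(sprintf("phase %s interventional treatment study", phase[i]),
              sample(pool, k - 1, replace = k - 1 > length(pool)))
    type <- c("+", ifelse(grepl("^exclusion", sent[-1]), "-", "+"))
    jsonlite::toJSON(data.frame(type = type, text = sent), auto_unbox = TRUE)
  }, character(1))

  window <- as.numeric(diff(config$date_window))
  start <- config$date_window[1] + floor(stats::runif(n) * (window + 1))
  completion <- start + 180 + floor(stats::runif(n) * 551)  # 0.5-2 years

  trials <- data.frame(
    trial_id = sprintf("TRIAL%05d", seq_len(n)),
    smiles = vapply(drugs, paste, character(1), collapse = ";"),
    icd_codes = vapply(dis, paste, character(1), collapse = ";"),
    criteria = criteria,
    phase = phase,
    start_date = as.character(start),
    completion_date = as.character(completion),
    label = label,
    stringsAsFactors = FALSE)

  truth <- structure(list(
    latent_score = stats::qlogis(pmin(pmax(bayes_prob, 1e-12), 1 - 1e-12)),
    bayes_prob = bayes_prob,
    molecule_attrs = attrs,
    disease_risk = risk,
    protocol_quality = quality,
    protocol_score = prot_score,
    noise_sd = noise_sd,
    phase_offsets = offsets), class = "planted_truth")

  list(trials = trials, ontology = onto, truth = truth)
}

#' Expected AUC of a set of conditional success probabilities
#'
#' For labels drawn as Bernoulli(p), the expected AUC of the score p itself:
#' a weighted Mann-Whitney statistic with positive mass p and negative mass
#' 1 - p per sample (ties at equal p counted half).
#'
#' @param p Vector of probabilities.
#' @return Expected AUC.
#' @keywords internal
expected_auc_weighted <- function(p) {
  ord <- order(p)
  p <- p[ord]
  w1 <- p; w0 <- 1 - p
  grp <- cumsum(c(TRUE, diff(p) != 0))
  g0 <- tapply(w0, grp, sum)           # negative mass per distinct value
  g1 <- tapply(w1, grp, sum)
  below0 <- cumsum(c(0, g0[-length(g0)]))
  num <- sum(g1 * (below0 + 0.5 * g0))
  num / (sum(w1) * sum(w0))
}

#' Generate the five auxiliary ADMET property tables
#'
#' One row per vocabulary molecule and property: binary label obtained by
#' thresholding the planted attribute at 0.5, then flipping with the given
#' noise probability.  Deterministic given the config seed.
#'
#' @param config A [synth_config()].
#' @param truth The \code{planted_truth} from [gen_trials()].
#' @param flip_noise Label-flip probability in \[0, 0.5\].
#' @return Named list (A, D, M, E, T) of data.frames (smiles, label).
#' @export
gen_admet_tables <- function(config, truth, flip_noise = 0.05) {
  stopifnot(inherits(truth, "planted_truth"),
            flip_noise >= 0, flip_noise <= 0.5)
  set.seed(config$seed + 1L)
  attrs <- truth$molecule_attrs
  out <- lapply(colnames(attrs), function(p) {
    lab <- as.integer(attrs[, p] > 0.5)
    flip <- stats::rbinom(length(lab), 1, flip_noise) == 1
    lab[flip] <- 1L - lab[flip]
    data.frame(smiles = rownames(attrs), label = lab,
               stringsAsFactors = FALSE)
  })
  stats::setNames(out, colnames(attrs))
}

#' Sampler of scored samples with confidence-correlated errors
#'
#' Returns a closure drawing i.i.d. (probability, label) pairs from a
#' miscalibrated-noise model: a latent z ~ N(0,1) drives both the model
#' probability plogis(slope_model * z) and the truth Bernoulli(plogis(
#' slope_truth * z)).  The slopes differ, so the reported probability is
#' miscalibrated, while errors still concentrate at low confidence -- the
#' regime selective classification exploits.  The defaults make the model
#' underconfident (truth slope steeper), so high-confidence subsets are
#' markedly more accurate than full coverage.
#'
#' @param slope_model,slope_truth Logistic slopes of the model score and the
#'   true conditional probability.
#' @return Function(n) returning a data.frame (prob_success, true_label);
#'   uses the caller's RNG stream.
#' @export
scored_sample_generator <- function(slope_model = 2, slope_truth = 3) {
  force(slope_model); force(slope_truth)
  function(n) {
    z <- stats::rnorm(n)
    data.frame(prob_success = stats::plogis(slope_model * z),
               true_label = stats::rbinom(n, 1, stats::plogis(slope_truth * z)))
  }
}
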