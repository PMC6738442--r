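#' @keywords internal
lr <- function(x) as.vector(vapply(x, function(s) paste0(s, c(" (L)", " (R)")),
                                   character(2)))

jhu_tracts <- function() {
  unpaired <- c("Middle cerebellar peduncle", "Pontine crossing tract",
                "Genu of corpus callosum", "Body of corpus callosum",
                "Splenium of corpus callosum", "Fornix")
  paired <- c("Corticospinal tract", "Medial lemniscus",
              "Inferior cerebellar peduncle", "Superior cerebellar peduncle",
              "Cerebral peduncle", "Anterior limb of internal capsule",
              "Posterior limb of internal capsule",
              "Retrolenticular part of internal capsule",
              "Anterior corona radiata", "Superior corona radiata",
              "Posterior corona radiata", "Posterior thalamic radiation",
              "Sagittal stratum", "External capsule",
              "Cingulum (cingulate gyrus)", "Cingulum (hippocampus)",
              "Fornix (cres) / Stria terminalis",
              "Superior longitudinal fasciculus",
              "Superior fronto-occipital fasciculus",
              "Uncinate fasciculus", "Tapetum")
  c(unpaired, lr(paired)) # 6 + 42 = 48
}

ho_cortical <- function() {
  c("Frontal Pole", "Insular Cortex", "Superior Frontal Gyrus",
    "Middle Frontal Gyrus", "Inferior Frontal Gyrus, pars triangularis",
    "Inferior Frontal Gyrus, pars opercularis", "Precentral Gyrus",
    "Temporal Pole", "Superior Temporal Gyrus, anterior",
    "Superior Temporal Gyrus, posterior", "Middle Temporal Gyrus, anterior",
    "Middle Temporal Gyrus, posterior",
    "Middle Temporal Gyrus, temporooccipital",
    "Inferior Temporal Gyrus, anterior", "Inferior Temporal Gyrus, posterior",
    "Inferior Temporal Gyrus, temporooccipital", "Postcentral Gyrus",
    "Superior Parietal Lobule", "Supramarginal Gyrus, anterior",
    "Supramarginal Gyrus, posterior", "Angular Gyrus",
    "Lateral Occipital Cortex, superior", "Lateral Occipital Cortex, inferior",
    "Intracalcarine Cortex", "Frontal Medial Cortex",
    "Juxtapositional Lobule Cortex", "Subcallosal Cortex",
    "Paracingulate Gyrus", "Cingulate Gyrus, anterior",
    "Cingulate Gyrus, posterior", "Precuneous Cortex", "Cuneal Cortex",
    "Frontal Orbital Cortex", "Parahippocampal Gyrus, anterior",
    "Parahippocampal Gyrus, posterior", "Lingual Gyrus",
    "Temporal Fusiform Cortex, anterior", "Temporal Fusiform Cortex, posterior",
    "Temporal Occipital Fusiform Cortex", "Occipital Fusiform Gyrus",
    "Frontal Operculum Cortex", "Central Opercular Cortex",
    "Parietal Operculum Cortex", "Planum Polare", "Heschl's Gyrus",
    "Planum Temporale", "Supracalcarine Cortex", "Occipital Pole")
}

#' Default IDP manifest
#'
#' Per-variable metadata for the 453 imaging-derived phenotypes across five
#' modality blocks: SIENAX global tissue volumes (10), FIRST subcortical
#' structure volumes (15), FAST grey-matter ROI volumes (139, split into
#' non-cerebellum and cerebellum subdomains), BIANCA white-matter
#' hyperintensity load (1), and TBSS diffusivity summaries within 48 major
#' white-matter tracts for each of six indices FA, MO, MD, L1, L2, L3 (288).
#' Polarity marks whether a higher value is a favourable marker (+1) or an
#' unfavourable one (-1): ventricular CSF, WMH load and the diffusivity
#' magnitudes MD/L1/L2/L3 carry polarity -1.
#'
#' @return Data frame with columns `variable`, `block`, `subdomain`,
#'   `polarity`, `levels`.
#' @export
idp_manifest <- function() {
  sienax_base <- c("Brain volume", "Grey matter volume",
                   "White matter volume", "Peripheral cortical GM volume",
                   "Ventricular CSF volume")
  sienax <- data.frame(
    variable = paste0("SIENAX ", rep(sienax_base, each = 2),
                      rep(c(", norm", ", unnorm"), 5)),
    block = "SIENAX", subdomain = "global_volume",
    polarity = rep(ifelse(grepl("CSF", sienax_base), -1, 1), each = 2))

  first_structs <- c("Brain-Stem", lr(c("Thalamus", "Caudate", "Putamen",
                                        "Pallidum", "Hippocampus", "Amygdala",
                                        "Accumbens")))
  first <- data.frame(
    variable = paste0("FIRST Volume of ", first_structs),
    block = "FIRST", subdomain = "subcortical_volume", polarity = 1)

  noncereb <- c(lr(ho_cortical()),
                lr(c("Thalamus", "Caudate", "Putamen", "Pallidum",
                     "Hippocampus", "Amygdala", "Accumbens")),
                "Brain-Stem GM")
  cereb_lobules <- c("I-IV", "V", "VI", "Crus I", "Crus II", "VIIb",
                     "VIIIa", "VIIIb", "IX", "X")
  cereb <- c(lr(paste("Cerebellum", cereb_lobules)),
             paste("Vermis", c("VI", "Crus I", "Crus II", "VIIb",
                               "VIIIa", "VIIIb", "IX", "X")))
  fast <- data.frame(
    variable = paste0("Volume of GM in ", c(noncereb, cereb)),
    block = "FAST",
    subdomain = rep(c("gm_noncerebellum", "gm_cerebellum"),
                    c(length(noncereb), length(cereb))),
    polarity = 1)

  bianca <- data.frame(variable = "Total WMH volume", block = "BIANCA",
                       subdomain = "wmh", polarity = -1)

  indices <- c(FA = 1, MO = 1, MD = -1, L1 = -1, L2 = -1, L3 = -1)
  tbss <- do.call(rbind, lapply(names(indices), function(ix) {
    data.frame(variable = paste0(ix, " in ", jhu_tracts()),
               block = "TBSS", subdomain = paste0("tbss_", tolower(ix)),
               polarity = indices[[ix]])
  }))

  man <- rbind(sienax, first, fast, bianca, tbss)
  man$levels <- NA_integer_
  rownames(man) <- NULL
  stopifnot(nrow(man) == 453L, sum(man$block == "TBSS") == 288L)
  man
}

#' Default non-IDP manifest
#'
#' Per-variable metadata for the 70 non-imaging measures: 31 cognitive, 8
#' demographic, 22 health and 9 lifestyle variables. Polarity -1 flags
#' variables where a lower value is the favourable outcome (latencies,
#' error counts, depression scores, disease prevalences, smoking load,
#' sleep-quality index). `levels` gives the number of ordinal levels for
#' survey items emulated by thresholding a continuous latent; NA means
#' continuous.
#'
#' @return Data frame with columns `variable`, `block`, `subdomain`,
#'   `polarity`, `levels`.
#' @export
nonidp_manifest <- function() {
  cog <- data.frame(
    variable = c("IQ-11", "IQ-20", "IQ-57", "IQ-63",
                 "PAL first trial memory score", "PAL total errors adjusted",
                 "PAL total trials adjusted",
                 "PRM percent correct", "PRM SD correct latency",
                 "SRM percent correct", "SRM SD correct latency",
                 "MOT mean error", "MOT mean latency",
                 "RTI mean 5-choice movement time",
                 "RTI mean 5-choice reaction time",
                 "RVP A' score", "RVP mean latency block 1",
                 "RVP mean latency block 2", "RVP mean latency block 3",
                 "RVP mean latency block 4",
                 "ACE total score", "MMSE total score",
                 "SOC problems solved in minimum moves", "SOC mean 5-moves",
                 "SOC mean initial thinking time 5-moves",
                 "SOC mean subsequent thinking time 5-moves",
                 "Word pairs learning", "Word pairs retention",
                 "Digit symbol modalities", "Trail making A", "Trail making B"),
    subdomain = "cognition",
    polarity = c(1, 1, 1, 1,
                 1, -1, -1,
                 1, -1, 1, -1,
                 -1, -1, -1, -1,
                 1, -1, -1, -1, -1,
                 1, 1, 1, -1, -1, -1,
                 -1, -1, 1, -1, -1),
    levels = NA_integer_)
  # word-pairs scores count failures (higher in decliners), hence -1

  dem <- data.frame(
    variable = c("Subject SEP", "Paternal SEP", "Civil status (non-single)",
                 "Offspring (yes)", "School years", "Education attainment",
                 "Birth length", "Birth weight"),
    subdomain = "demographic",
    polarity = c(1, 1, 1, 1, 1, 1, 1, 1),
    levels = c(4L, 3L, 2L, 2L, NA, NA, NA, NA))

  ncd <- c("Asthma", "Cancer", "Cardiovascular disease",
           "Cerebrovascular disease", "Depression", "Diabetes",
           "Hypercholesterolemia", "Hypertension", "Migraine",
           "Prolapsed disc")
  fam <- c("Cardiovascular disease", "Cerebrovascular disease", "Dementia",
           "Diabetes", "Depression", "Hypertension", "Myocardial infarct")
  health <- data.frame(
    variable = c(paste("Self-reported", ncd),
                 paste("Familial", fam),
                 "BMI", "Height", "MDI score", "Cerebral blood flow",
                 "Total cholesterol"),
    subdomain = "health",
    polarity = c(rep(-1, length(ncd)), rep(-1, length(fam)),
                 -1, 1, -1, 1, -1),
    levels = c(rep(2L, length(ncd) + length(fam)), NA, NA, NA, NA, NA))

  life <- data.frame(
    variable = c("Alcohol status (yes)", "Alcohol start age",
                 "Alcohol units per week", "Exercise frequency",
                 "Smoking status (yes)", "Smokes pack-years",
                 "Smoking start age", "Smoking stop age", "PSQI"),
    subdomain = "lifestyle",
    polarity = c(-1, 1, -1, 1, -1, -1, 1, 1, -1),
    levels = c(2L, NA, NA, 6L, 2L, NA, NA, NA, NA))

  man <- rbind(cog, dem, health, life)
  man$block <- man$subdomain
  man <- man[, c("variable", "block", "subdomain", "polarity", "levels")]
  rownames(man) <- NULL
  stopifnot(nrow(man) == 70L, sum(man$subdomain == "cognition") == 31L,
            sum(man$subdomain == "demographic") == 8L,
            sum(man$subdomain == "health") == 22L,
            sum(man$subdomain == "lifestyle") == 9L)
  man
}
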