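# Published summary values from the AaDOP2 antagonist discovery campaign,
# transcribed as typed tables. These are inputs to the analysis chain
# (selectivity, rank-correlation, and recovery scenarios), not outputs.

#' Reported agonist potencies at the mosquito dopamine receptors
#'
#' EC50 values (mean +/- SEM over independent experiments, in nM) for
#' biogenic amines and synthetic agonists at AaDOP1 and AaDOP2,
#' heterologously expressed with a CRE-luciferase reporter. Entries at or
#' above 10 uM are censored: such compounds are considered to lack
#' intrinsic activity.
#'
#' @return A tibble with `compound`, `receptor`, `ec50_nM`, `sem_nM`,
#'   `censored`.
#' @export
reference_agonist_potencies <- function() {
  rows <- list(
    c("dopamine",       3.1,  1.1, 240, 16),
    c("epinephrine",    5.8,  1.5, NA,  NA),
    c("norepinephrine", 760,  180, NA,  NA),
    c("histamine",      NA,   NA,  NA,  NA),
    c("octopamine",     NA,   NA,  NA,  NA),
    c("serotonin",      NA,   NA,  NA,  NA),
    c("tyramine",       NA,   NA,  NA,  NA),
    c("dihydrexidine",  6.9,  1.5, 290, 54),
    c("SKF81297",       24,   7.0, NA,  NA),
    c("SKF38393",       310,  46,  NA,  NA))
  long <- lapply(rows, function(r) {
    tibble::tibble(
      compound = rep(r[1], 2),
      receptor = c("AaDOP1", "AaDOP2"),
      ec50_nM = as.numeric(c(r[2], r[4])),
      sem_nM = as.numeric(c(r[3], r[5])))
  })
  out <- dplyr::bind_rows(long)
  out$censored <- is.na(out$ec50_nM)
  out
}

#' Reported confirmation IC50s at AaDOP2 and the human D1 receptor
#'
#' Antagonist IC50s (mean +/- SEM, nM) from cAMP-accumulation
#' confirmation assays in the presence of 3 uM dopamine (AaDOP2) or
#' 100 nM dopamine (hD1), together with the published fold-selectivity
#' column. Compounds censored at AaDOP2 (>= 10 uM; the off-target
#' reporter chemistries niclosamide, piceatannol, resveratrol) were not
#' tested at hD1.
#'
#' @return A tibble with `compound`, `ic50_aadop2_nM`, `sem_aadop2_nM`,
#'   `ic50_hd1_nM`, `sem_hd1_nM`, `reported_fold_selectivity`,
#'   `censored_aadop2`.
#' @export
reference_confirmation_potencies <- function() {
  out <- tibble::tribble(
    ~compound,              ~ic50_aadop2_nM, ~sem_aadop2_nM, ~ic50_hd1_nM, ~sem_hd1_nM, ~reported_fold_selectivity,
    "amitriptyline",        14,   3.4,  470,  49,   36,
    "(+)-butaclamol",       480,  33,   3.7,  0.64, 0.008,
    "cis-(Z)-flupenthixol", 20,   5.4,  11,   1.9,  0.55,
    "clozapine",            31,   6.5,  300,  35,   9.7,
    "doxepin",              31,   4.9,  960,  86,   31,
    "methiothepin",         14,   5.1,  80,   11,   5.7,
    "mianserin",            120,  40,   1200, 260,  10,
    "niclosamide",          NA,   NA,   NA,   NA,   NA,
    "piceatannol",          NA,   NA,   NA,   NA,   NA,
    "resveratrol",          NA,   NA,   NA,   NA,   NA,
    "SCH23390",             1600, 73,   0.47, 0.03, 0.0003)
  out$censored_aadop2 <- is.na(out$ic50_aadop2_nM)
  out
}

#' Reported screen hits with their mechanism classes
#'
#' The 51 compounds called as AaDOP2 antagonist hits at the
#' mean-minus-3-SD threshold, each with its percent of the SCH23390
#' control effect and its mechanism class (the seven-class partition of
#' [hit_classes()]).
#'
#' @return A tibble with `compound`, `hit_class`,
#'   `pct_of_control_effect`.
#' @export
reference_screen_hits <- function() {
  dar <- c("R(+)-SCH-23390" = 83, "(+/-)-butaclamol" = 81, "(+)-butaclamol" = 87,
           "chlorprothixene" = 94, "clozapine" = 81, "fluphenazine" = 82,
           "cis-(Z)-flupenthixol" = 88, "JL-18" = 98, "LE 300" = 99,
           "loxapine" = 97, "(+/-)-octoclothepin" = 97, "perphenazine" = 95,
           "prochlorperazine" = 83, "promazine" = 88, "propionylpromazine" = 85,
           "risperidone" = 83, "triflupromazine" = 88, "trifluoperazine" = 81,
           "thiothixene" = 86, "thioridazine" = 86)
  ser <- c("amperozide" = 83, "LY-310,762" = 81, "mianserin" = 95,
           "methiothepin" = 99, "pirenperone" = 90, "ritanserin" = 83)
  his <- c("ketotifen" = 96, "promethazine" = 95)
  ach <- c("benztropine" = 89)
  upt <- c("amitriptyline" = 90, "amoxapine" = 90,
           "4'-chloro-3-alpha-(diphenylmethoxy)tropane" = 85, "doxepin" = 90,
           "imipramine" = 96, "maprotiline" = 82, "nortriptyline" = 96,
           "protriptyline" = 82, "trimipramine" = 87)
  kin <- c("diacylglycerol kinase inhibitor I" = 90, "kenpaullone" = 83,
           "NSC 95397" = 83, "piceatannol" = 98,
           "phorbol 12-myristate 13-acetate" = 88, "purvalanol A" = 93)
  mis <- c("beta-lapachone" = 86, "(S)-(+)-camptothecin" = 93, "emetine" = 86,
           "idarubicin" = 83, "mitoxantrone" = 83, "niclosamide" = 95,
           "resveratrol" = 89)
  groups <- list(dopamine_receptor_antagonist = dar,
                 serotonin_receptor_ligand = ser,
                 histamine_receptor_ligand = his,
                 machr_ligand = ach,
                 uptake_inhibitor = upt,
                 protein_kinase_modulator = kin,
                 miscellaneous = mis)
  dplyr::bind_rows(lapply(names(groups), function(cl) {
    tibble::tibble(compound = names(groups[[cl]]), hit_class = cl,
                   pct_of_control_effect = unname(groups[[cl]]))
  }))
}
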