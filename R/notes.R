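# Templated clinical narratives: consultation, progression, procedural and
# radiology notes for a synthetic case. Each note opens with a structured
# header (subtype, dementia-risk category), plants sentiment-consistent
# lexicon terms, states the lesion-size trajectory, and is padded with
# neutral clinical filler to the 400-900 whitespace-token range typical of
# generated notes.

NOTE_KINDS <- c("consultation", "progression", "procedural", "radiology")

SUBTYPE_NAMES <- c(
  ICH = "intracerebral hemorrhage", SDH = "subdural hemorrhage",
  EDH = "extradural hemorrhage", IVH = "intraventricular hemorrhage",
  SAH = "subarachnoid hemorrhage", Mixed = "mixed intracranial hemorrhage")

.note_headers <- c(
  consultation = "consultation note for patient %s . history and physical examination reviewed on admission . working diagnosis : %s . dementia and alzheimer risk category : %s .",
  progression = "progression note for patient %s . interval neurological findings and serial imaging reviewed . established diagnosis : %s . dementia and alzheimer risk category : %s .",
  procedural = "procedural note for patient %s . operative approach , intraoperative findings and postoperative monitoring documented . indication : %s . dementia and alzheimer risk category : %s .",
  radiology = "radiology impression for patient %s . axial brain mr slices compared with prior studies . finding : %s . dementia and alzheimer risk category : %s .")

# Sentiment-keyed sentence fragments; each draws >=1 phrase from the
# matching lexicon list so lexicon_sentiment can recover the evidence.
.prognosis_sentences <- list(
  positive = c(
    "the clinical trajectory suggests a favorable outcome with steady recovery .",
    "serial examinations indicate improved survival and a good outcome is anticipated .",
    "the neurological status is stable and recovery is expected to continue ."),
  negative = c(
    "imaging demonstrates a large hematoma and the depressed level of consciousness borders on coma .",
    "old age and a large hematoma burden weigh against meaningful recovery of function .",
    "extension toward a posterior fossa hemorrhage pattern would carry a grave outlook ."),
  neutral = c(
    "assessment tracks the glasgow coma scale , hematoma volume and midline shift without clear directional change .",
    "the ich score , mass effect and perihematomal edema are documented for longitudinal comparison .",
    "supratentorial location is noted ; hematoma volume is followed on serial imaging ."),
  uncertain = c(
    "findings remain equivocal and the prognosis cannot be stated with confidence at this interval .",
    "the direction of change is indeterminate pending further imaging correlation ."))

.therapeutic_sentences <- list(
  positive = c(
    "response to intervention has been encouraging with a stable postoperative course and early recovery .",
    "treatment achieved a good outcome so far with improved survival expected under continued care ."),
  negative = c(
    "despite maximal therapy a large hematoma persists and sedation approaches a coma state .",
    "therapeutic options are constrained by old age and the refractory hematoma burden ."),
  neutral = c(
    "management is guided by the glasgow coma scale and interval hematoma volume measurements .",
    "supportive therapy continues while midline shift and mass effect are monitored ."),
  uncertain = c(
    "benefit from the current regimen is not yet established and will be reassessed .",
    "the therapeutic response is indeterminate at this time ."))

.filler_bank <- c(
  "vital signs were within acceptable limits throughout the observation period .",
  "the patient was monitored in the neurological intensive care unit with hourly checks .",
  "laboratory values including coagulation profile were reviewed and corrected as needed .",
  "blood pressure was managed with titratable intravenous agents per protocol .",
  "no new focal deficit was elicited on the most recent structured examination .",
  "the family was updated regarding the current findings and the plan of care .",
  "analgesia and sedation were adjusted to permit serial neurological assessment .",
  "prophylaxis against venous thromboembolism was continued per institutional guideline .",
  "electrolytes and osmotherapy targets were reviewed twice daily by the team .",
  "the airway remained protected and oxygen saturation was maintained on minimal support .",
  "nutrition was advanced as tolerated with aspiration precautions in place .",
  "physical and occupational therapy consultations were placed for early mobilization .",
  "repeat imaging has been scheduled to document interval change in the lesion .",
  "the nursing staff documented no seizure activity during the reporting interval .",
  "temperature was controlled and infectious surveillance cultures remained negative .",
  "medication reconciliation was completed and home medications were resumed where appropriate .",
  "the multidisciplinary team discussed disposition planning during morning rounds .",
  "intracranial pressure readings remained within the target range on current therapy .",
  "pupillary responses were brisk and symmetric on serial bedside checks .",
  "fluid balance was reviewed and diuresis adjusted to maintain euvolemia .",
  "the operative site remained clean and dry with no drainage noted .",
  "social work was engaged to support the family through the hospital course .",
  "follow up appointments were arranged with neurology and neurosurgery clinics .",
  "the documentation was reviewed and electronically signed by the attending physician .")

.note_template_words <- function() {
  txt <- c(.note_headers, unlist(.prognosis_sentences),
           unlist(.therapeutic_sentences), .filler_bank,
           SUBTYPE_NAMES, "high", "moderate", "low", "to",
           "reiterated", "care", "planning", "surveillance", "intensity",
           "reflects", "subtype", "trajectory", "enlarged", "remained",
           "unchanged", "partially", "resorbed", "continued", "enlarge",
           "across", "interval", "in",
           "estimated", "lesion", "area", "by", "time", "frame", "px",
           "prognosis", "therapeutic", "impression", "sentiment",
           "patient", "case")
  unlist(strsplit(tolower(txt), "\\s+"))
}

#' Generate a templated clinical note for a synthetic case
#'
#' Deterministic for a fixed seed. The note embeds the subtype name, the
#' dementia-risk category, the lesion-area trajectory across frames, and
#' sentiment-consistent lexicon terms (a case with positive prognosis draws
#' from the positive lexicon, and so on). Whitespace token count always
#' lands in `[400, 900]`.
#'
#' @param case A case record (see [build_manifest()]).
#' @param kind One of `"consultation"`, `"progression"`, `"procedural"`,
#'   `"radiology"`.
#' @param seed Integer run seed.
#' @return Character scalar: the note text.
#' @export
generate_clinical_note <- function(case, kind, seed = 0L) {
  if (!kind %in% NOTE_KINDS)
    stop("unknown note kind '", kind, "'; valid kinds: ",
         paste(NOTE_KINDS, collapse = ", "))
  with_seed(substream_seed(seed, paste0("note-", case$case_id, "-", kind)), {
    header <- sprintf(.note_headers[[kind]], case$case_id,
                      SUBTYPE_NAMES[[case$subtype]],
                      tolower(case$risk_level))
    a <- case$areas
    mid <- ceiling(length(a) / 2)
    early_ph <- if (a[mid] > a[1] * 1.05) "enlarged"
      else "remained unchanged in size"
    late_ph <- if (a[length(a)] < a[mid] * 0.95) "partially resorbed"
      else if (a[length(a)] > a[mid] * 1.05) "continued to enlarge"
      else "remained unchanged in size"
    traj <- sprintf(
      "hematoma size trajectory : the lesion %s across the early interval and %s across the late interval .",
      early_ph, late_ph)
    prog <- sample(.prognosis_sentences[[case$prognosis_sentiment]], 1L)
    ther <- sample(.therapeutic_sentences[[case$therapeutic_sentiment]], 1L)
    risk <- tolower(case$risk_level)
    body <- c(header, traj,
              paste("prognosis assessment :", prog),
              sprintf("the dementia and alzheimer risk category is reiterated as %s for care planning .", risk),
              paste("therapeutic assessment :", ther),
              sprintf("surveillance intensity reflects the %s dementia risk category for this subtype .", risk))
    n_words <- function(x) sum(lengths(strsplit(x, "\\s+")))
    while (n_words(paste(body, collapse = " ")) < 430)
      body <- c(body, sample(.filler_bank, 1L))
    paste(body, collapse = " ")
  })
}
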