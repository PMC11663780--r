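#' Construct a phrase bank
#'
#' A phrase bank holds the building blocks of synthetic note sections:
#' positive cue phrases in five categories (concern, symptom, diagnosis,
#' assessment, therapy), hard-negative cue phrases in five categories
#' (improvement, transient, reversible, negated, uncertain) and clinically
#' neutral filler sentences. Construction validates the bank against the
#' screening lexicon: every cue phrase — positive or hard-negative — must
#' contain at least one expert keyword (so keyword screening retains every
#' cue-bearing section and cannot trivially separate the classes), and no
#' filler sentence may contain any.
#'
#' @param positive_cues Named list of character vectors; names must be
#'   `concern`, `symptom`, `diagnosis`, `assessment`, `therapy`.
#' @param hard_negative_cues Named list of character vectors; names must be
#'   `improvement`, `transient`, `reversible`, `negated`, `uncertain`.
#' @param filler_sentences Character vector of neutral sentences.
#' @param lexicon Screening lexicon used for validation; defaults to the
#'   shipped expert lexicon.
#' @return A `phrase_bank` object (a validated list).
#' @export
phrase_bank <- function(positive_cues, hard_negative_cues, filler_sentences,
                        lexicon = read_lexicon()) {
  pos_cats <- c("concern", "symptom", "diagnosis", "assessment", "therapy")
  neg_cats <- c("improvement", "transient", "reversible", "negated",
                "uncertain")
  if (!setequal(names(positive_cues), pos_cats)) {
    stop("positive_cues must have categories: ",
         paste(pos_cats, collapse = ", "), call. = FALSE)
  }
  if (!setequal(names(hard_negative_cues), neg_cats)) {
    stop("hard_negative_cues must have categories: ",
         paste(neg_cats, collapse = ", "), call. = FALSE)
  }
  if (any(lengths(positive_cues) == 0L) ||
      any(lengths(hard_negative_cues) == 0L) ||
      length(filler_sentences) == 0L) {
    stop("phrase bank categories must be non-empty", call. = FALSE)
  }
  all_cues <- c(unlist(positive_cues, use.names = FALSE),
                unlist(hard_negative_cues, use.names = FALSE))
  hit <- lexicon_matches(all_cues, lexicon, source = "expert")
  if (!all(hit)) {
    stop("cue phrase contains no lexicon keyword: ",
         sQuote(all_cues[!hit][1L]), call. = FALSE)
  }
  filler_hit <- lexicon_matches(filler_sentences, lexicon, source = "expert")
  if (any(filler_hit)) {
    stop("filler sentence contains a lexicon keyword: ",
         sQuote(filler_sentences[filler_hit][1L]), call. = FALSE)
  }
  structure(list(positive_cues = positive_cues,
                 hard_negative_cues = hard_negative_cues,
                 filler_sentences = filler_sentences),
            class = "phrase_bank")
}

#' The default phrase bank
#'
#' Positive cues cover the five ways cognitive decline is documented in
#' notes: caregiver concerns, symptoms (e.g. memory loss), diagnoses
#' (e.g. MCI, Alzheimer's disease dementia), cognitive assessments
#' (e.g. Mini-Cog, MoCA) and cognition-directed therapies. Hard negatives
#' cover the annotation rules for negative cases: improving, transient
#' (e.g. codeine-induced forgetfulness), reversible (e.g. post-surgery
#' confusion), negated and uncertain mentions — each still carrying a
#' screening keyword. Fillers are neutral clinical sentences free of
#' screening keywords.
#'
#' @param lexicon Screening lexicon used for validation.
#' @return A `phrase_bank`.
#' @export
default_phrase_bank <- function(lexicon = read_lexicon()) {
  phrase_bank(
    positive_cues = list(
      concern = c(
        "Family raises concerns about progressive memory loss at home.",
        "Patient reports worsening forgetfulness over the past year.",
        "Daughter is worried that attention and recall have faded noticeably.",
        "Spouse describes growing trouble with memory for appointments."),
      symptom = c(
        "Patient exhibits short term memory loss and misplaces objects daily.",
        "Episodes of confusion and disorientation reported by staff.",
        "Noticeable word finding difficulties during conversation.",
        "Forgetting names of close relatives has become frequent.",
        "Increasing agitation in the evenings with poor recall of recent events."),
      diagnosis = c(
        "Assessment consistent with mild cognitive impairment.",
        "Diagnosis of early Alzheimer's disease dementia discussed with family.",
        "Meets criteria for major neurocognitive disorder, likely vascular dementia.",
        "Progressive cognitive decline consistent with amnestic MCI."),
      assessment = c(
        "Mini-Cog screening abnormal; formal cognitive evaluation ordered.",
        "MoCA score of 21 out of 30 indicates impairment.",
        "MMSE completed today showing poor delayed recall.",
        "Montreal cognitive assessment scheduled to quantify memory deficits.",
        "Neuropsychological evaluation shows decline in executive function."),
      therapy = c(
        "Started on donepezil for symptomatic dementia management.",
        "Referred to cognitive-linguistic therapy for memory strategies.",
        "Aricept dose increased given progressive memory impairment.",
        "Enrolled in a memory clinic program for cognitive rehabilitation.")),
    hard_negative_cues = list(
      improvement = c(
        "Cognitive function improvement noted since the last visit.",
        "Memory has improved markedly following rehabilitation.",
        "Attention span is better than at the prior evaluation."),
      transient = c(
        "Temporary forgetfulness due to codeine, expected to resolve.",
        "Occasional memory lapses attributed to new opioid medication.",
        "Brief confusion overnight that cleared by morning."),
      reversible = c(
        "Mild confusion shortly after surgery, fully resolved before discharge.",
        "Disorientation following anesthesia resolved within hours.",
        "Delirium in the setting of urinary infection, now cleared."),
      negated = c(
        "No evidence of memory loss or cognitive decline on review.",
        "Patient denies any problems with memory or attention.",
        "Neurological exam normal with no cognitive deficits identified."),
      uncertain = c(
        "Possible memory changes of unclear significance, will monitor.",
        "Vague report of forgetfulness, not corroborated by family.",
        "Borderline MoCA score of uncertain clinical relevance.")),
    filler_sentences = c(
      "Blood pressure 128 over 76, heart rate 72 and regular.",
      "Patient denies chest pain, fever, or shortness of breath.",
      "Medication list reviewed and reconciled with the pharmacy record.",
      "Lungs clear to auscultation bilaterally without wheezes.",
      "Follow up visit scheduled in three months with primary care.",
      "Ambulating independently without an assistive device.",
      "Diet counseling provided regarding sodium restriction.",
      "Laboratory results reviewed; electrolytes within normal limits.",
      "Influenza vaccination administered in the left deltoid.",
      "Abdomen soft, nontender, with normal bowel sounds.",
      "Skin warm and dry without rash or lesions.",
      "Continues home regimen of lisinopril and metformin without side effects.",
      "Knee pain improved with physical therapy exercises.",
      "Hemoglobin A1c stable at 6.8 percent this quarter.",
      "Routine colonoscopy due next year per screening guidelines."),
    lexicon = lexicon)
}

#' Which hard-negative category, if any, a text carries
#'
#' Detects the first hard-negative cue phrase of the bank present verbatim
#' (case-insensitive) in the text.
#'
#' @param text Character vector of section texts.
#' @param bank A `phrase_bank`.
#' @return Character vector of category names, `NA` where none found.
#' @export
detect_hard_negative_category <- function(text, bank) {
  lower <- tolower(text)
  out <- rep(NA_character_, length(text))
  for (cat in names(bank$hard_negative_cues)) {
    for (cue in bank$hard_negative_cues[[cat]]) {
      hit <- is.na(out) & grepl(tolower(cue), lower, fixed = TRUE)
      out[hit] <- cat
    }
  }
  out
}

#' Does a text contain any positive cue of the bank?
#'
#' @param text Character vector of section texts.
#' @param bank A `phrase_bank`.
#' @return Logical vector.
#' @export
contains_positive_cue <- function(text, bank) {
  lower <- tolower(text)
  cues <- tolower(unlist(bank$positive_cues, use.names = FALSE))
  out <- rep(FALSE, length(text))
  for (cue in cues) out <- out | grepl(cue, lower, fixed = TRUE)
  out
}
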