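# Subject vitals: the clinical measurements that parameterize the Windkessel
# outlet model (pressures, heart rate, stroke volume) plus cohort labels.

#' Construct subject vitals
#'
#' @param systolic Systolic blood pressure, mmHg.
#' @param diastolic Diastolic blood pressure, mmHg; must be below systolic.
#' @param heart_rate Heart rate, beats/min.
#' @param stroke_volume Stroke volume, mL.
#' @param group_label One of `"caw"` (carotid web), `"atherosclerosis"`,
#'   `"normal"`.
#' @param event_label Logical; prior TIA/stroke event.
#' @param subject_id Optional identifier string.
#' @return An object of class `subject_vitals`. Pulse pressure and mean
#'   arterial pressure are derived quantities, never stored.
#' @export
subject_vitals <- function(systolic, diastolic, heart_rate, stroke_volume,
                           group_label = c("caw", "atherosclerosis", "normal"),
                           event_label = FALSE, subject_id = NA_character_) {
  group_label <- match.arg(group_label)
  if (!is.numeric(systolic) || !is.numeric(diastolic) ||
      systolic <= diastolic || diastolic <= 0)
    stop("require systolic > diastolic > 0 (mmHg)", call. = FALSE)
  if (!is.numeric(heart_rate) || heart_rate <= 0)
    stop("`heart_rate` must be positive", call. = FALSE)
  if (!is.numeric(stroke_volume) || stroke_volume <= 0)
    stop("`stroke_volume` must be positive", call. = FALSE)
  structure(list(systolic = systolic, diastolic = diastolic,
                 heart_rate = heart_rate, stroke_volume = stroke_volume,
                 group_label = group_label, event_label = isTRUE(event_label),
                 subject_id = subject_id),
            class = "subject_vitals")
}

#' Pulse pressure
#'
#' Systolic minus diastolic pressure, mmHg.
#' @param vitals A [subject_vitals()] object.
#' @return Pulse pressure, mmHg.
#' @export
pulse_pressure <- function(vitals) {
  stopifnot(inherits(vitals, "subject_vitals"))
  vitals$systolic - vitals$diastolic
}

#' Read subject vitals from a YAML file
#'
#' Expected keys: `systolic_mmHg`, `diastolic_mmHg`, `heart_rate_bpm`,
#' `stroke_volume_mL`, `group`, `event`; optional `subject_id`.
#'
#' @param path YAML file path.
#' @return A [subject_vitals()] object.
#' @export
read_subject_vitals <- function(path) {
  y <- yaml::read_yaml(path)
  need <- c("systolic_mmHg", "diastolic_mmHg", "heart_rate_bpm",
            "stroke_volume_mL", "group", "event")
  missing <- setdiff(need, names(y))
  if (length(missing))
    stop("vitals YAML missing keys: ", paste(missing, collapse = ", "), call. = FALSE)
  subject_vitals(y$systolic_mmHg, y$diastolic_mmHg, y$heart_rate_bpm,
                 y$stroke_volume_mL, y$group, isTRUE(y$event),
                 subject_id = if (is.null(y$subject_id)) NA_character_ else y$subject_id)
}

#' Write subject vitals to a YAML file
#'
#' @param vitals A [subject_vitals()] object.
#' @param path Output YAML path.
#' @return `path`, invisibly.
#' @export
write_subject_vitals <- function(vitals, path) {
  stopifnot(inherits(vitals, "subject_vitals"))
  yaml::write_yaml(list(systolic_mmHg = vitals$systolic,
                        diastolic_mmHg = vitals$diastolic,
                        heart_rate_bpm = vitals$heart_rate,
                        stroke_volume_mL = vitals$stroke_volume,
                        group = vitals$group_label,
                        event = vitals$event_label,
                        subject_id = vitals$subject_id),
                   path)
  invisible(path)
}
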