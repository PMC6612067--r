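# fixture builders shared across test files; everything is generated in code

make_visits <- function(patient_id, visit_type = "soc",
                        admission_date = "2006-01-10",
                        discharge_date = NA_character_,
                        cost = 100, primary_diagnosis = "R69",
                        medications = "", subsidised = TRUE,
                        short_stay = FALSE, visit_id = NULL) {
  n <- if (length(patient_id) == 0L) 0L else {
    max(lengths(list(patient_id, visit_type, admission_date, cost)))
  }
  df <- data.frame(
    patient_id = rep_len(patient_id, n),
    visit_id = if (is.null(visit_id)) sprintf("V%04d", seq_len(n)) else visit_id,
    visit_type = rep_len(visit_type, n),
    admission_date = as.Date(rep_len(admission_date, n)),
    discharge_date = as.Date(rep_len(discharge_date, n)),
    cost = rep_len(cost, n),
    primary_diagnosis = rep_len(primary_diagnosis, n),
    medications = rep_len(medications, n),
    subsidised = rep_len(subsidised, n),
    short_stay = rep_len(short_stay, n),
    stringsAsFactors = FALSE)
  df
}

make_patients <- function(patient_id, birth_date = "1960-01-01",
                          gender = "female", race = "chinese",
                          nationality = "singaporean",
                          housing_type = "flat_3room_plus",
                          death_date = NA_character_) {
  n <- length(patient_id)
  data.frame(
    patient_id = patient_id,
    birth_date = as.Date(rep_len(birth_date, n)),
    gender = rep_len(gender, n),
    race = rep_len(race, n),
    nationality = rep_len(nationality, n),
    housing_type = rep_len(housing_type, n),
    death_date = as.Date(rep_len(death_date, n)),
    stringsAsFactors = FALSE)
}

# a minimal patient-year aggregate table for threshold/classification tests
make_agg <- function(cost = 0, los = 0, soc = 0, admissions = NULL,
                     patient_id = NULL) {
  n <- max(lengths(list(cost, los, soc)))
  cost <- rep_len(cost, n); los <- rep_len(los, n); soc <- rep_len(soc, n)
  if (is.null(admissions)) admissions <- as.integer(los > 0)
  data.frame(
    patient_id = if (is.null(patient_id)) sprintf("P%04d", seq_len(n)) else patient_id,
    cost_total = cost, los_total = los, soc_visits = soc,
    admissions = rep_len(admissions, n),
    ed_attendances = 0L,
    had_admission = rep_len(admissions, n) > 0,
    stringsAsFactors = FALSE)
}

# a hand-built hu_segmentation object for profiling tests
make_seg <- function(segmentation, aggregates_y1) {
  structure(list(segmentation = segmentation, aggregates_y1 = aggregates_y1,
                 counts = table(segmentation$group), q = 0.9),
            class = "hu_segmentation")
}

empty_visits_df <- function() make_visits(character(0))

packaged_quan <- function() {
  load_code_mapping(system.file("extdata", "quan_ccmi_toy.csv",
                                package = "husegment"), kind = "quan")
}

packaged_ccs <- function() {
  load_code_mapping(system.file("extdata", "ccs_toy.csv",
                                package = "husegment"), kind = "ccs")
}
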