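# In-code fixtures: a tiny hand-constructed raw-record collection.

fixture_patient <- function(id, birth = "1950-06-15", sex = "male",
                            practice = "prA") {
  tibble::tibble(patient_id = id, practice_id = practice,
                 birth_date = as.Date(birth), sex = sex)
}

# registration covering 2013Q1..2018Q4; `absent` = follow-up quarter indices
# (1-based from 2014Q1) with missing registration
fixture_registration <- function(id, absent = integer(0)) {
  qs <- seq(as.Date("2013-01-01"), by = "quarter", length.out = 24)
  fu_idx <- seq_along(qs) - 4L
  tibble::tibble(patient_id = rep(id, each = 24),
                 quarter_start = rep(qs, length(id)),
                 present = rep(!(fu_idx %in% absent), length(id)))
}

empty_episodes <- tibble::tibble(patient_id = character(), code = character(),
                                 start_date = as.Date(character()))
empty_meas <- tibble::tibble(patient_id = character(), kind = character(),
                             value = character(), date = as.Date(character()))
empty_rx <- tibble::tibble(patient_id = character(), atc_code = character(),
                           date = as.Date(character()))

# one patient with measurements, morbidity episodes and a prescription
fixture_records_single <- function() {
  ehr_records(
    patients = fixture_patient("p1"),
    episodes = tibble::tibble(
      patient_id = c("p1", "p1"),
      code = c("T90", "K86"),
      start_date = as.Date(c("2010-05-01", "2014-03-01"))),
    measurements = tibble::tibble(
      patient_id = "p1",
      kind = c("sbp_mmHg", "sbp_mmHg", "height_cm", "weight_kg", "dbp_mmHg"),
      value = c("150", "140", "178", "84.5", "88"),
      date = as.Date(c("2013-02-01", "2013-12-20", "2013-06-01",
                       "2013-06-01", "2013-12-20"))),
    prescriptions = tibble::tibble(
      patient_id = "p1", atc_code = "C07AB02",
      date = as.Date("2013-09-15")),
    registration = fixture_registration("p1"),
    window_start = as.Date("2000-01-01"))
}

# eligibility fixture: 10 patients with known violations
# p01 fine | p02 aged 39 | p03 prevalent AF 2012 | p04 missing a 2013 quarter
# p05 fine | p06 aged 12 | p07 prevalent AF 2013 | p08 practice prB has no
# follow-up data (p08, p09 both in prB) | p10 fine
fixture_records_flow <- function() {
  pts <- dplyr::bind_rows(
    fixture_patient("p01", "1950-01-15"),
    fixture_patient("p02", "1974-06-01"), # 39 at baseline
    fixture_patient("p03", "1940-02-02"),
    fixture_patient("p04", "1955-03-03"),
    fixture_patient("p05", "1948-04-04"),
    fixture_patient("p06", "2001-05-05"), # 12 at baseline
    fixture_patient("p07", "1939-07-07"),
    fixture_patient("p08", "1952-08-08", practice = "prB"),
    fixture_patient("p09", "1953-09-09", practice = "prB"),
    fixture_patient("p10", "1960-10-10"))
  reg <- dplyr::bind_rows(
    fixture_registration("p01"),
    fixture_registration("p02"),
    fixture_registration("p03"),
    # p04 misses 2013 Q2 (fu index -2)
    fixture_registration("p04", absent = -2L),
    fixture_registration("p05"),
    fixture_registration("p06"),
    fixture_registration("p07"),
    # practice prB: absent for the whole follow-up
    fixture_registration("p08", absent = 1:20),
    fixture_registration("p09", absent = 1:20),
    fixture_registration("p10"))
  eps <- tibble::tibble(
    patient_id = c("p03", "p07"),
    code = "K78",
    start_date = as.Date(c("2012-06-01", "2013-11-01")))
  ehr_records(pts, eps, empty_meas, empty_rx, reg,
              window_start = as.Date("2000-01-01"))
}
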