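# Privacy-role map over the full OMOP CDM v5.2 schema: 45 PHIs and 17 QIs.
# The exact published variable list for the full CDM is not public; entries
# beyond the SynPUF 5% subset are a best-effort reconstruction following the
# same rules (all event dates/datetimes and geographic subdivisions below
# state are PHIs; standard concept-id analysis variables are clinical QIs).
# Edit freely: the loader only enforces internal consistency, while the
# package test suite pins this shipped profile at 45 PHIs / 17 QIs.
profile_name: omop_full
cdm_version: '5.2'
variables:
- {table: person, column: month_of_birth, role: PHI, value_kind: code, mask_rule: suppress}
- {table: person, column: day_of_birth, role: PHI, value_kind: code, mask_rule: suppress}
- {table: person, column: birth_datetime, role: PHI, value_kind: date, mask_rule: year_only}
- {table: death, column: death_date, role: PHI, value_kind: date, mask_rule: year_only}
- {table: death, column: death_datetime, role: PHI, value_kind: date, mask_rule: year_only}
- {table: visit_occurrence, column: visit_start_date, role: PHI, value_kind: date, mask_rule: year_only}
- {table: visit_occurrence, column: visit_start_datetime, role: PHI, value_kind: date, mask_rule: year_only}
- {table: visit_occurrence, column: visit_end_date, role: PHI, value_kind: date, mask_rule: year_only}
- {table: visit_occurrence, column: visit_end_datetime, role: PHI, value_kind: date, mask_rule: year_only}
- {table: condition_occurrence, column: condition_start_date, role: PHI, value_kind: date, mask_rule: year_only}
- {table: condition_occurrence, column: condition_start_datetime, role: PHI, value_kind: date, mask_rule: year_only}
- {table: condition_occurrence, column: condition_end_date, role: PHI, value_kind: date, mask_rule: year_only}
- {table: condition_occurrence, column: condition_end_datetime, role: PHI, value_kind: date, mask_rule: year_only}
- {table: drug_exposure, column: drug_exposure_start_date, role: PHI, value_kind: date, mask_rule: year_only}
- {table: drug_exposure, column: drug_exposure_start_datetime, role: PHI, value_kind: date, mask_rule: year_only}
- {table: drug_exposure, column: drug_exposure_end_date, role: PHI, value_kind: date, mask_rule: year_only}
- {table: drug_exposure, column: drug_exposure_end_datetime, role: PHI, value_kind: date, mask_rule: year_only}
- {table: procedure_occurrence, column: procedure_date, role: PHI, value_kind: date, mask_rule: year_only}
- {table: procedure_occurrence, column: procedure_datetime, role: PHI, value_kind: date, mask_rule: year_only}
- {table: device_exposure, column: device_exposure_start_date, role: PHI, value_kind: date, mask_rule: year_only}
- {table: device_exposure, column: device_exposure_start_datetime, role: PHI, value_kind: date, mask_rule: year_only}
- {table: device_exposure, column: device_exposure_end_date, role: PHI, value_kind: date, mask_rule: year_only}
- {table: device_exposure, column: device_exposure_end_datetime, role: PHI, value_kind: date, mask_rule: year_only}
- {table: measurement, column: measurement_date, role: PHI, value_kind: date, mask_rule: year_only}
- {table: measurement, column: measurement_datetime, role: PHI, value_kind: date, mask_rule: year_only}
- {table: observation, column: observation_date, role: PHI, value_kind: date, mask_rule: year_only}
- {table: observation, column: observation_datetime, role: PHI, value_kind: date, mask_rule: year_only}
- {table: specimen, column: specimen_date, role: PHI, value_kind: date, mask_rule: year_only}
- {table: specimen, column: specimen_datetime, role: PHI, value_kind: date, mask_rule: year_only}
- {table: note, column: note_date, role: PHI, value_kind: date, mask_rule: year_only}
- {table: note, column: note_datetime, role: PHI, value_kind: date, mask_rule: year_only}
- {table: observation_period, column: observation_period_start_date, role: PHI, value_kind: date, mask_rule: year_only}
- {table: observation_period, column: observation_period_end_date, role: PHI, value_kind: date, mask_rule: year_only}
- {table: payer_plan_period, column: payer_plan_period_start_date, role: PHI, value_kind: date, mask_rule: year_only}
- {table: payer_plan_period, column: payer_plan_period_end_date, role: PHI, value_kind: date, mask_rule: year_only}
- {table: condition_era, column: condition_era_start_date, role: PHI, value_kind: date, mask_rule: year_only}
- {table: condition_era, column: condition_era_end_date, role: PHI, value_kind: date, mask_rule: year_only}
- {table: drug_era, column: drug_era_start_date, role: PHI, value_kind: date, mask_rule: year_only}
- {table: drug_era, column: drug_era_end_date, role: PHI, value_kind: date, mask_rule: year_only}
- {table: location, column: address_1, role: PHI, value_kind: geography, mask_rule: suppress}
- {table: location, column: city, role: PHI, value_kind: geography, mask_rule: suppress}
- {table: location, column: zip, role: PHI, value_kind: geography, mask_rule: suppress}
- {table: location, column: county, role: PHI, value_kind: geography, mask_rule: suppress}
- {table: provider, column: npi, role: PHI, value_kind: identifier, mask_rule: suppress}
- {table: provider, column: dea, role: PHI, value_kind: identifier, mask_rule: suppress}
- {table: person, column: year_of_birth, role: QI_demographic, value_kind: year, mask_rule: none}
- {table: person, column: gender_concept_id, role: QI_demographic, value_kind: code, mask_rule: none}
- {table: person, column: race_concept_id, role: QI_demographic, value_kind: code, mask_rule: none}
- {table: person, column: ethnicity_concept_id, role: QI_demographic, value_kind: code, mask_rule: none}
- {table: location, column: state, role: QI_demographic, value_kind: code, mask_rule: none}
- {table: condition_occurrence, column: condition_concept_id, role: QI_clinical, value_kind: code, mask_rule: none}
- {table: procedure_occurrence, column: procedure_concept_id, role: QI_clinical, value_kind: code, mask_rule: none}
- {table: drug_exposure, column: drug_concept_id, role: QI_clinical, value_kind: code, mask_rule: none}
- {table: device_exposure, column: device_concept_id, role: QI_clinical, value_kind: code, mask_rule: none}
- {table: measurement, column: measurement_concept_id, role: QI_clinical, value_kind: code, mask_rule: none}
- {table: observation, column: observation_concept_id, role: QI_clinical, value_kind: code, mask_rule: none}
- {table: care_site, column: place_of_service_concept_id, role: QI_clinical, value_kind: code, mask_rule: none}
- {table: specimen, column: specimen_concept_id, role: QI_clinical, value_kind: code, mask_rule: none}
- {table: visit_occurrence, column: visit_concept_id, role: QI_clinical, value_kind: code, mask_rule: none}
- {table: condition_era, column: condition_concept_id, role: QI_clinical, value_kind: code, mask_rule: none}
- {table: drug_era, column: drug_concept_id, role: QI_clinical, value_kind: code, mask_rule: none}
- {table: note, column: note_type_concept_id, role: QI_clinical, value_kind: code, mask_rule: none}
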