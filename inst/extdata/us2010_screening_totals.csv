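# Published 2010 US totals for adults without diagnosed diabetes, used as
# inputs to the totals-level efficiency/coverage/opportunity operations.
# Units: thousands of persons. pc_* rows refer to persons with at least one
# primary-care office visit in 2010 and to the expected detectable cases
# among them. national_* rows are CDC national case totals for 2010.
measure,ada,uspstf
screened_total,86292,59064
detected_dm,4639,3735
detected_predm,33927,24407
pc_visit_patients,50180,41530
pc_detectable_dm,3083,2753
pc_detectable_predm,20386,17263.409
national_dm,7000,7000
national_predm,79000,79000
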