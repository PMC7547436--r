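column,units,description
patient_id,,Opaque patient identifier
age_at_listing,years,Recipient age when first waitlisted
epts,score,Estimated post-transplant survival score (lower = better expected recipient survival); synthetic monotone noisy function of recipient age
listed_time,years,Listing time measured from the study origin
transplant_time,years,Time from listing to deceased-donor transplant; empty if never transplanted
donor_age,years,Donor age; present if and only if transplanted
donor_kdri,score,Kidney donor risk index (higher = worse expected graft survival); synthetic monotone noisy function of donor age; present iff transplanted
graft_failure_time,years,Time from transplant to graft failure; empty if not observed
death_time,years,Time to death: from transplant if transplanted; from listing otherwise; empty if not observed
censor_time,years,Administrative censoring time from listing (study horizon minus listing time)
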