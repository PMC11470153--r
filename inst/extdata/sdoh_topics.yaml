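# Example SDOH topic lexicon (topic name -> keyword list).
# Synthetic seed lists for demonstration; supply your own lexicon for
# production analyses.
Mental health:
  - anxiety
  - depression
  - distress
  - coping
  - mood
  - counseling
Family:
  - family
  - daughter
  - husband
  - caregiver
  - children
Consultation/Appointment:
  - consultation
  - appointment
  - referral
  - scheduled
Group session:
  - group session
  - support group
  - workshop
Risk of death:
  - hospice
  - end of life
  - mortality
  - palliative
Clinician/Hospital/Medication:
  - physician
  - hospital
  - nurse
  - medication
  - oncologist
Living condition/Lifestyle/Social support:
  - housing
  - social support
  - lifestyle
  - homeless
  - transportation
  - living situation
Telephone encounter/Online communication:
  - telephone
  - phone call
  - voicemail
  - email
Abuse history:
  - abuse
  - domestic violence
  - trauma history
Insurance/Income:
  - insurance
  - income
  - financial
  - medicaid
  - copay
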