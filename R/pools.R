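# Versioned default term pools for the synthetic corpus generator.  The
# vocabulary of the real reporting systems is implicit in confidential data;
# these pools encode, per class, the kind of discriminative clinical
# vocabulary an incident narrative of that class would carry.  Pools are
# pairwise disjoint at the raw-token level (validated by the config
# constructor) so that an overlap-0 world is exactly separable.

#' Incident-type label scheme (10 priority types + Others)
#'
#' Order is fixed: it drives the DAG decision structure and all round-robin
#' tie-breaks.
#'
#' @return Character vector of the 11 incident-type labels.
#' @export
incident_type_labels <- function() {
  c("falls", "medications", "pressure_injury", "aggression",
    "documentation", "blood_product", "patient_identification",
    "infection", "clinical_handover", "deteriorating_patient", "others")
}

#' Severity label scheme (SAC1 extreme ... SAC4 low)
#'
#' @return Character vector `c("SAC1","SAC2","SAC3","SAC4")`.
#' @export
severity_labels <- function() c("SAC1", "SAC2", "SAC3", "SAC4")

default_type_pools <- function() {
  list(
    falls = c("fell", "slipped", "tripped", "stumbled", "floor", "fracture",
              "hip", "bruise", "unwitnessed", "mobility", "walking", "frame",
              "rail", "toileting", "balance", "dizzy", "commode",
              "laceration", "gait", "slippery", "footwear", "overbalanced"),
    medications = c("medication", "dose", "drug", "tablet", "insulin",
                    "warfarin", "antibiotic", "pharmacy", "prescription",
                    "omitted", "administered", "overdose", "milligrams",
                    "oral", "syringe", "dispensed", "penicillin", "morphine",
                    "paracetamol", "stat", "withheld", "ampoule"),
    pressure_injury = c("pressure", "ulcer", "sacrum", "heel", "redness",
                        "blister", "skin", "wound", "dressing", "mattress",
                        "repositioned", "bony", "tissue", "necrotic", "sore",
                        "buttock", "erythema", "offloading", "prominence",
                        "shear", "moisture", "debridement"),
    aggression = c("aggressive", "punched", "verbal", "abuse", "threatened",
                   "shouting", "security", "assault", "kicked", "bitten",
                   "restrained", "agitated", "violent", "behaviour",
                   "codeblack", "spat", "grabbed", "hostile", "weapon",
                   "deescalation", "intimidating", "outburst"),
    documentation = c("documentation", "form", "record", "consent",
                      "signature", "filed", "illegible", "entry", "notes",
                      "paperwork", "scanned", "incomplete", "checklist",
                      "addressograph", "misfiled", "archived", "photocopy",
                      "template", "field", "backdated", "unsigned", "label"),
    blood_product = c("transfusion", "platelets", "crossmatch", "packed",
                      "units", "haemoglobin", "plasma", "rhesus", "antibody",
                      "febrile", "haemolysis", "cryoprecipitate", "donor",
                      "compatibility", "bloodbank", "serology", "albumin",
                      "irradiated", "expiry", "fridge", "traceability",
                      "grouping"),
    patient_identification = c("identification", "wristband", "armband",
                               "identity", "misidentified", "bracelet",
                               "verified", "mismatch", "birthdate",
                               "surname", "specimen", "identifiers",
                               "urn", "alias", "twins", "namesake",
                               "photograph", "interpreter", "duplicate",
                               "registration", "merged", "demographic"),
    infection = c("infection", "sepsis", "swab", "culture", "mrsa",
                  "isolation", "precautions", "outbreak", "hygiene",
                  "contaminated", "cellulitis", "pneumonia", "organism",
                  "bacteraemia", "vre", "gastro", "norovirus", "sterile",
                  "asepsis", "colonised", "purulent", "immunocompromised"),
    clinical_handover = c("handover", "shift", "communicated", "escalated",
                          "briefing", "isbar", "relayed", "outgoing",
                          "incoming", "readback", "huddle", "rounds",
                          "succinct", "unrelayed", "nightshift",
                          "weekend", "covering", "locum", "pager",
                          "switchboard", "referral", "followup"),
    deteriorating_patient = c("deteriorating", "observations", "vitals",
                              "hypotension", "tachycardia", "unresponsive",
                              "newsscore", "met", "rapidresponse",
                              "saturation", "oxygen", "gcs", "drowsy",
                              "hypoxia", "bradycardia", "clammy", "pallor",
                              "rigors", "oliguria", "confusion", "lethargy",
                              "desaturation"),
    others = c("equipment", "delay", "appointment", "catering", "cleaning",
               "maintenance", "property", "telephone", "wheelchair",
               "environment", "spillage", "parking", "lift", "airconditioning",
               "linen", "waste", "supplies", "stores", "courier", "booking",
               "rostering", "valuables")
  )
}

default_severity_pools <- function() {
  list(
    SAC1 = c("extreme", "fatality", "arrest", "resuscitation", "coroner",
             "critical", "irreversible", "catastrophic", "morgue",
             "rootcause", "sentinel", "disaster"),
    SAC2 = c("major", "surgery", "disability", "permanent", "icu",
             "intervention", "serious", "prolonged", "executive",
             "disclosure", "specialist", "urgent"),
    SAC3 = c("moderate", "treatment", "clinic", "xray", "suturing",
             "analgesia", "extended", "monitoring", "bandage",
             "reassessment", "graze", "outpatient"),
    SAC4 = c("minor", "trivial", "nil", "nearmiss", "avoided", "caught",
             "intercepted", "noharm", "inconvenience", "minimal",
             "unaffected", "administrative")
  )
}

# Severity-indicative keyword phrases; the extreme-risk pool follows the
# published keyword structure (death, suicide, high risk, police notified,
# incorrect patient, infection, blood transfusion reaction, aggression).
default_severity_keywords <- function() {
  list(
    SAC1 = c("death", "suicide", "high risk", "police notified",
             "incorrect patient", "infection", "blood transfusion reaction",
             "aggression"),
    SAC2 = c("emergency surgery", "transferred icu", "serious harm",
             "permanent harm", "medical emergency"),
    SAC3 = c("required sutures", "extra observation", "short delay",
             "first aid", "pain relief"),
    SAC4 = c("no harm", "near miss", "no injury", "minimal impact",
             "error intercepted")
  )
}

default_shared_pool <- function() {
  c("patient", "ward", "nurse", "doctor", "staff", "review", "noted",
    "reported", "incident", "care", "hospital", "clinical", "family",
    "informed", "plan", "assessment", "continued", "stable", "bed",
    "morning", "overnight", "afternoon", "evening", "registrar", "team",
    "unit", "theatre", "emergency", "department", "admitted", "discharged",
    "condition", "comfortable", "settled", "routine", "checked", "advised",
    "discussed", "completed", "commenced", "ceased", "ongoing", "attended",
    "summary", "manager", "contacted", "requested", "arranged",
    "explained", "apologised", "reassured", "hourly", "chart",
    "progress", "history", "regular", "follow", "today", "yesterday",
    "later")
}
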