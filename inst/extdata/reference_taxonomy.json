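{
  "name": "pdsentinel reference deviation taxonomy (synthetic)",
  "note": "Synthetic two-level vocabulary of common protocol-deviation themes used by the narrative generator and the deterministic mock extraction backend. It is a stand-in built for testing, not an expert-curated operational taxonomy.",
  "categories": [
    {
      "category": "Sample Collection and Laboratory Issues",
      "topics": [
        {
          "topic": "sample collection timing",
          "keyphrases": ["blood sample drawn outside the collection window", "sample collected at the wrong time point"]
        },
        {
          "topic": "sample handling and storage",
          "keyphrases": ["specimen stored at an incorrect temperature", "sample left unprocessed beyond the stability limit"]
        },
        {
          "topic": "missed laboratory assessment",
          "keyphrases": ["required laboratory panel was not performed"]
        }
      ]
    },
    {
      "category": "Informed Consent and Documentation",
      "topics": [
        {
          "topic": "informed consent timing",
          "keyphrases": ["consent form signed late", "consent obtained after study procedures began"]
        },
        {
          "topic": "consent version control",
          "keyphrases": ["outdated consent form version used"]
        },
        {
          "topic": "missing source documentation",
          "keyphrases": ["source document could not be located"]
        }
      ]
    },
    {
      "category": "Visit Scheduling and Timing",
      "topics": [
        {
          "topic": "visit outside protocol window",
          "keyphrases": ["visit occurred outside the protocol specified window"]
        },
        {
          "topic": "missed study visit",
          "keyphrases": ["participant missed the scheduled study visit"]
        },
        {
          "topic": "assessment sequence error",
          "keyphrases": ["assessments performed in the wrong order"]
        }
      ]
    },
    {
      "category": "Medication Administration",
      "topics": [
        {
          "topic": "incorrect dose administered",
          "keyphrases": ["study drug administered at an incorrect dose"]
        },
        {
          "topic": "dosing schedule deviation",
          "keyphrases": ["dose given outside the dosing window"]
        },
        {
          "topic": "drug storage excursion",
          "keyphrases": ["study drug stored outside the required temperature range"]
        }
      ]
    },
    {
      "category": "Adverse Event Reporting",
      "topics": [
        {
          "topic": "late adverse event reporting",
          "keyphrases": ["adverse event reported outside the required timeframe"]
        },
        {
          "topic": "missed adverse event assessment",
          "keyphrases": ["adverse event follow-up assessment was not completed"]
        },
        {
          "topic": "serious adverse event documentation",
          "keyphrases": ["serious adverse event narrative lacked required detail"]
        }
      ]
    }
  ]
}
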