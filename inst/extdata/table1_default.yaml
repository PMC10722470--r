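# Default computational phenotype history: quarterly keyword / ICD-10-CM
# adjustments for the human-trafficking risk phenotype, as published.
#
# Conventions:
#   - keyword patterns are stored lowercase; '%' is a SQL-LIKE wildcard for
#     any character run within one word token
#   - sex_scope defaults to "any"; the complete female-specific list was
#     never published, so the general list is scoped "any"
#   - codes default to prefix matching (a recorded T74.21XA matches pattern
#     T74.21); descriptions are kept so they can be evaluated as key
#     phrases against diagnosis description text from 2019-10-01 onward
#     (the "simplified to key phrase" change)
#   - "rapped (sp)" is stored as the literal misspelling trap "rapped";
#     the "(sp)" annotation is not match text
#   - "black eye" is never printed as an addition but is documented as
#     subtracted from the male list in 2020 Q1; it is added here with the
#     2019 Q3 general vocabulary and re-scoped to female_only in 2020 Q1
#     so that removal is expressible against an active pattern
#   - Z91.41 carries its printed mid-quarter date (added 7-22-19) as its
#     own version; all other entries take their quarter's first day
#   - Z91.42 is printed four times; duplicates collapse at assembly

match_code_descriptions_from: "2019-10-01"

versions:
  - id: 2019Q3
    effective_from: "2019-07-01"
    add_keywords:
      - {pattern: abdominal}
      - {pattern: abuse}
      - {pattern: abusive}
      - {pattern: anorexia}
      - {pattern: assault}
      - {pattern: black eye}
      - {pattern: contusion}
      - {pattern: dehydration}
      - {pattern: exploitation}
      - {pattern: malnutrition}
      - {pattern: maltreatment}
      - {pattern: neglect}
      - {pattern: trauma}
    add_codes:
      - {code: "O9A.4", description: "Sexual abuse complicating pregnancy, childbirth, and the puerperium"}
      - {code: "T74.21", description: "Adult sexual abuse, confirmed"}
      - {code: "T74.22", description: "Child sexual abuse, confirmed"}
      - {code: "T74.51", description: "Adult forced sexual exploitation, confirmed"}
      - {code: "T74.52", description: "Child sexual exploitation, confirmed"}
      - {code: "T74.61", description: "Adult forced labor exploitation, confirmed"}
      - {code: "T74.62", description: "Child forced labor exploitation, confirmed"}
      - {code: "T76.12", description: "Current child sexual abuse"}
      - {code: "T76.21", description: "Adult sexual abuse, suspected"}
      - {code: "T76.21 XA", description: "Adult sexual abuse, suspected, initial encounter"}
      - {code: "T76.22", description: "Child sexual abuse, suspected"}
      - {code: "T76.51", description: "Adult forced sexual exploitation, suspected"}
      - {code: "T76.52", description: "Child sexual exploitation, suspected"}
      - {code: "T76.61", description: "Adult forced labor exploitation, suspected"}
      - {code: "T76.62", description: "Child forced labor exploitation, suspected"}
      - {code: "Y07.6", description: "Multiple perpetrators of maltreatment and neglect"}
      - {code: "Z04.81", description: "Encounter for examination and observation of victim following forced sexual exploitation"}
      - {code: "Z04.82", description: "Encounter for examination and observation of victim following forced labor exploitation"}
      - {code: "Z62.81", description: "Personal history of physical and sexual abuse in childhood"}
      - {code: "Z62.813", description: "Personal history of forced labor or sexual exploitation in childhood"}
      - {code: "Z91.4", description: "Personal history of psychological trauma, not elsewhere classified"}
      - {code: "Z91.411", description: "Personal history of adult psychological abuse"}
      - {code: "Z91.412", description: "Personal history of adult neglect"}
      - {code: "Z91.419", description: "Personal history of unspecified adult abuse"}
      - {code: "Z91.42", description: "Personal history of forced labor or sexual exploitation"}
      - {code: "Z91.42", description: "Personal history of forced labor or sexual exploitation"}
      - {code: "Z91.42", description: "Personal history of forced labor or sexual exploitation"}
      - {code: "Z91.42", description: "Personal history of forced labor or sexual exploitation"}

  - id: 2019Q3-midq
    effective_from: "2019-07-22"
    add_codes:
      - {code: "Z91.41", description: "Personal history of adult abuse"}

  - id: 2019Q4
    effective_from: "2019-10-01"
    add_keywords:
      - {pattern: adult abuse}
      - {pattern: aids}
      - {pattern: anal}
      - {pattern: anus}
      - {pattern: cws}
      - {pattern: dysuria}
      - {pattern: farm worker}
      - {pattern: field worker}
      - {pattern: "force%"}
      - {pattern: forced labor}
      - {pattern: gonorrhea}
      - {pattern: "herpe%"}
      - {pattern: hiv}
      - {pattern: laborer}
      - {pattern: migrant}
      - {pattern: neglect}
      - {pattern: physical abuse}
      - {pattern: physical and sexual abuse}
      - {pattern: "psych%"}
      - {pattern: psychological abuse}
      - {pattern: psychological trauma}
      - {pattern: rectum}
      - {pattern: run away}
      - {pattern: runaway}
      - {pattern: "sex%"}
      - {pattern: sexual abuse}
      - {pattern: "suicid%"}
      - {pattern: syphilis}
      - {pattern: "traffic%"}
      - {pattern: trans-sexual}
      - {pattern: transgender}
      - {pattern: transsexual}
      - {pattern: transvestite}
      - {pattern: troubled teen}
      - {pattern: urinary tract}
      - {pattern: "vagin%"}
      - {pattern: violence}

  - id: 2020Q1
    effective_from: "2020-01-01"
    add_keywords:
      - {pattern: pelvic}
      - {pattern: perineal}
      - {pattern: perineum}
      - {pattern: ptsd}
      - {pattern: stress disorder}
      - {pattern: transgender}
      - {pattern: transsexual}
      - {pattern: trans-sexual}
      - {pattern: transvestite}
      # male-specific list
      - {pattern: penis, sex_scope: male_only}
      - {pattern: "testic%", sex_scope: male_only}
      # "black eye" subtracted as nonspecific for males: the any-scope
      # entry is removed and re-added for females only
      - {pattern: black eye, sex_scope: female_only}
    remove_keywords:
      - {pattern: black eye, sex_scope: any}

  - id: 2020Q2
    effective_from: "2020-04-01"
    add_keywords:
      - {pattern: rape}
      - {pattern: raped}
      - {pattern: rapped}
      - {pattern: molestation}
      - {pattern: molested}

  - id: 2020Q4
    effective_from: "2020-10-01"
    add_keywords:
      - {pattern: pushed by}
      - {pattern: struck by husband}
      - {pattern: struck by wife}
      - {pattern: struck by spouse}
      - {pattern: struck by boyfriend}
      - {pattern: struck by girlfriend}
      - {pattern: struck by significant other}
      - {pattern: struck by so}

  - id: 2021Q2
    effective_from: "2021-04-01"
    add_keywords:
      - {pattern: safe house}
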