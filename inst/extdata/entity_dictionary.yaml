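# Funder entity dictionary: every textual variant of the cola-brand funding
# universe, grouped by role. Variants are matched case-insensitively,
# longest-first, non-overlapping.
entities:
  - canonical: The Coca-Cola Company
    group: parent_company
    variants:
      - The Coca-Cola Company
      - Coca-Cola Company
      - Coca-Cola Co.
      - Coca-Cola
      - Coca Cola
      - CocaCola
  - canonical: The Coca-Cola Foundation
    group: foundation
    variants:
      - The Coca-Cola Foundation
      - Coca-Cola Foundation
  - canonical: Beverage Institute for Health and Wellness
    group: institute_bihw
    variants:
      - Beverage Institute for Health and Wellness
      - Beverage Institute of Health and Wellness
      - Beverage Institute for Health & Wellness
  - canonical: Coca-Cola North America
    group: north_america
    variants:
      - Coca-Cola North America
      - Coca-Cola Refreshments USA
  - canonical: Coca-Cola France
    group: subsidiary_participating
    variants:
      - Coca-Cola France
  - canonical: Coca-Cola Germany
    group: subsidiary_participating
    variants:
      - Coca-Cola Germany
      - Coca-Cola Deutschland
      - Coca-Cola GmbH
  - canonical: Coca-Cola Spain
    group: subsidiary_participating
    variants:
      - Coca-Cola Spain
      - Coca-Cola Iberia
      - Coca-Cola Espana
  - canonical: Coca-Cola New Zealand
    group: subsidiary_participating
    variants:
      - Coca-Cola New Zealand
      - Coca-Cola Oceania
  - canonical: Coca-Cola Australia
    group: subsidiary_participating
    variants:
      - Coca-Cola Australia
      - Coca-Cola South Pacific
  - canonical: Coca-Cola Brasil
    group: subsidiary_nonparticipating
    variants:
      - Coca-Cola Brasil
      - Coca-Cola Brazil
  - canonical: Coca-Cola Hellas
    group: subsidiary_nonparticipating
    variants:
      - Coca-Cola Hellas
      - Coca-Cola Hellenic
  - canonical: Coca-Cola Japan
    group: subsidiary_nonparticipating
    variants:
      - Coca-Cola Japan
      - Coca-Cola (Japan) Company
  - canonical: Coca-Cola India
    group: subsidiary_nonparticipating
    variants:
      - Coca-Cola India
  - canonical: Coca-Cola China
    group: subsidiary_nonparticipating
    variants:
      - Coca-Cola China
      - Coca-Cola Greater China
  - canonical: Coca-Cola Bottling Company
    group: subsidiary_nonparticipating
    variants:
      - Coca-Cola Bottling Company
      - Coca-Cola Bottlers
  - canonical: Pepsi-Cola
    group: other_cola
    variants:
      - Pepsi-Cola
      - Pepsi Cola
      - PepsiCo
  - canonical: RC Cola
    group: other_cola
    variants:
      - RC Cola
      - Royal Crown Cola
  - canonical: Inca Kola
    group: other_cola
    variants:
      - Inca Kola
      - Inca Cola
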