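# Field-matching vocabulary. Each field maps to PCRE-style regex strings
# applied to uppercased, whitespace-normalized OCR text. Extend or override
# entries (e.g. for new vendors or languages) and load with read_vocabulary().
# Capture-group contracts: clock.hm -> (hour)(minute); clock.oclock -> (hour);
# distance -> (number in cm). Quadrant-style location notation (LOQ, RIQ, ...)
# is deliberately absent: only ACR-recommended clock-face notation is parsed.
laterality:
  LEFT:
    - "\\bLEFT\\b"
    - "\\bLT\\b"
    - "\\bL(?=\\s+(?:BREAST|AX\\w*))"
  RIGHT:
    - "\\bRIGHT\\b"
    - "\\bRT\\b"
    - "\\bR(?=\\s+(?:BREAST|AX\\w*))"
orientation:
  ARAD:
    - "\\bARAD\\b"
    - "\\bANTI[- ]?RAD(?:IAL)?\\b"
    - "\\bANTIRAD(?:IAL)?\\b"
  RAD:
    - "\\bRAD(?:IAL)?\\b"
  TRANS:
    - "\\bTRANS(?:VERSE)?\\b"
    - "\\bTRV\\b"
  LONG:
    - "\\bLONG(?:ITUDINAL)?\\b"
  SAG:
    - "\\bSAG(?:ITTAL)?\\b"
  OBL:
    - "\\bOBL(?:IQUE)?\\b"
clock:
  hm:
    - "\\b(1[0-2]|[1-9])[:.]([0-5][0-9])\\b"
  oclock:
    - "\\b(1[0-2]|[1-9])\\s*O'?\\s?CLOCK\\b"
distance:
  - "\\b(\\d+(?:\\.\\d+)?)\\s*CM\\s*FN\\b"
  - "\\b(\\d+(?:\\.\\d+)?)CMFN\\b"
  - "\\b(\\d+(?:\\.\\d+)?)\\s*CM\\s+FROM\\s+(?:THE\\s+)?NIPPLE\\b"
axilla:
  - "\\bAXILLA\\b"
  - "\\bAXILLARY\\b"
  - "\\bAX\\b"
measurement:
  pair:
    - "\\b(\\d+(?:\\.\\d+)?)\\s*X\\s*(\\d+(?:\\.\\d+)?)\\s*CM\\b"
  single:
    - "\\b(\\d+(?:\\.\\d+)?)\\s*CM\\b"
procedural:
  - "\\bBIOPSY\\b"
  - "\\bBX\\b"
  - "\\bFNA\\b"
  - "\\bASPIRATION\\b"
  - "\\bCYST\\s+ASP\\b"
  - "\\bCLIP\\b"
  - "\\bMARKER\\b"
  - "\\bCOIL\\b"
  - "\\bWIRE\\b"
  - "\\bPOST\\s+BX\\b"
  - "\\bPRE\\s+BX\\b"
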