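indicator_id,name,description,existence_anchor,specificity_anchor,operability_anchor
1,confidentiality,Commitment to keep counseling content confidential,0 absent as independent item; 1 explicit independent item,0 none; 1 partial detail; 2 concrete detail,0 no procedure; 1 partial procedure; 2 actionable procedure
2,exceptions to confidentiality,Situations in which confidentiality may be broken (risk of harm or legal duty),0 absent as independent item; 1 explicit independent item,0 none; 1 partial detail; 2 concrete detail,0 no procedure; 1 partial procedure; 2 actionable procedure
3,client rights,Rights of the client including information and autonomy,0 absent as independent item; 1 explicit independent item,0 none; 1 partial detail; 2 concrete detail,0 no procedure; 1 partial procedure; 2 actionable procedure
4,guardian consent,Consent arrangements for minors or clients with guardians,0 absent as independent item; 1 explicit independent item,0 none; 1 partial detail; 2 concrete detail,0 no procedure; 1 partial procedure; 2 actionable procedure
5,goals and scope,Goals of counseling and the scope of the service,0 absent as independent item; 1 explicit independent item,0 none; 1 partial detail; 2 concrete detail,0 no procedure; 1 partial procedure; 2 actionable procedure
6,format and frequency,Session format and expected frequency or duration,0 absent as independent item; 1 explicit independent item,0 none; 1 partial detail; 2 concrete detail,0 no procedure; 1 partial procedure; 2 actionable procedure
7,fees and cancelation policy,Fees charged and the cancelation or no-show policy,0 absent as independent item; 1 explicit independent item,0 none; 1 partial detail; 2 concrete detail,0 no procedure; 1 partial procedure; 2 actionable procedure
8,recording methods,Whether and how sessions are recorded or documented,0 absent as independent item; 1 explicit independent item,0 none; 1 partial detail; 2 concrete detail,0 no procedure; 1 partial procedure; 2 actionable procedure
9,authorization and revocation,How consent is given and how it can be withdrawn,0 absent as independent item; 1 explicit independent item,0 none; 1 partial detail; 2 concrete detail,0 no procedure; 1 partial procedure; 2 actionable procedure
10,crisis procedures,Procedures for crisis or emergency situations,0 absent as independent item; 1 explicit independent item,0 none; 1 partial detail; 2 concrete detail,0 no procedure; 1 partial procedure; 2 actionable procedure
11,complaints and appeals,Channels for complaints and appeals,0 absent as independent item; 1 explicit independent item,0 none; 1 partial detail; 2 concrete detail,0 no procedure; 1 partial procedure; 2 actionable procedure
12,data protection,Storage and protection of records and personal data,0 absent as independent item; 1 explicit independent item,0 none; 1 partial detail; 2 concrete detail,0 no procedure; 1 partial procedure; 2 actionable procedure
13,disclaimer of boundaries,Boundaries of the counseling relationship and service,0 absent as independent item; 1 explicit independent item,0 none; 1 partial detail; 2 concrete detail,0 no procedure; 1 partial procedure; 2 actionable procedure
14,language clarity,Plain and unambiguous wording of the form itself,0 absent as independent item; 1 explicit independent item,0 none; 1 partial detail; 2 concrete detail,0 no procedure; 1 partial procedure; 2 actionable procedure
15,voluntariness,Statement that participation is voluntary,0 absent as independent item; 1 explicit independent item,0 none; 1 partial detail; 2 concrete detail,0 no procedure; 1 partial procedure; 2 actionable procedure
16,client obligations,Obligations and expected conduct of the client,0 absent as independent item; 1 explicit independent item,0 none; 1 partial detail; 2 concrete detail,0 no procedure; 1 partial procedure; 2 actionable procedure
17,counseling limitations,Limits of what counseling can achieve,0 absent as independent item; 1 explicit independent item,0 none; 1 partial detail; 2 concrete detail,0 no procedure; 1 partial procedure; 2 actionable procedure
18,counselor qualifications,Qualifications and supervision of the counselor,0 absent as independent item; 1 explicit independent item,0 none; 1 partial detail; 2 concrete detail,0 no procedure; 1 partial procedure; 2 actionable procedure
19,counseling modalities,Modalities or approaches offered,0 absent as independent item; 1 explicit independent item,0 none; 1 partial detail; 2 concrete detail,0 no procedure; 1 partial procedure; 2 actionable procedure
20,target population,Who the service is intended for,0 absent as independent item; 1 explicit independent item,0 none; 1 partial detail; 2 concrete detail,0 no procedure; 1 partial procedure; 2 actionable procedure
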