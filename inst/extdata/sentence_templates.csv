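set,label,kind,text
neutral,active_mb,plain,Massive hemorrhage with hemodynamic shock required urgent transfusion.
neutral,active_mb,plain,Acute massive bleeding caused severe anemia and shock overnight.
neutral,active_mb,plain,Large intracranial hemorrhage was confirmed on imaging today.
neutral,active_mb,plain,Profuse hemorrhage required several units transfused in emergency.
neutral,active_mb,plain,Severe hemorrhagic shock developed with massive blood loss.
neutral,active_mb,plain,Critical hemorrhage with rapid hemoglobin collapse was treated urgently.
neutral,active_crnmb,plain,Minor epistaxis episode resolved spontaneously without intervention.
neutral,active_crnmb,plain,Mild rectal bleeding with small oozing was noted on examination.
neutral,active_crnmb,plain,Limited hematuria observed and monitored without transfusion.
neutral,active_crnmb,plain,Small subcutaneous hematoma with mild oozing appeared on the arm.
neutral,active_crnmb,plain,Moderate melena episode settled with conservative measures.
neutral,active_crnmb,plain,Minor gum bleeding occurred after brushing and stopped quickly.
neutral,antecedent,plain,History of bleeding episode documented two years before admission.
neutral,antecedent,plain,Previous gastrointestinal hemorrhage reported long before this stay.
neutral,antecedent,plain,Known prior hemorrhage in the past medical record was noted.
neutral,antecedent,plain,Patient recalled an old bleeding event from a former hospitalization.
neutral,antecedent,plain,Past hemorrhagic episode predates the current admission clearly.
neutral,irrelevant,plain,Routine cardiac follow up showed stable vital signs today.
neutral,irrelevant,plain,Medication list reviewed and diet tolerated well overnight.
neutral,irrelevant,plain,Physiotherapy continued with good mobilization progress.
neutral,irrelevant,plain,Renal function remained stable throughout the stay.
neutral,irrelevant,plain,Discharge planning discussed with the family yesterday.
neutral,irrelevant,plain,Blood pressure controlled with unchanged treatment.
neutral,irrelevant,plain,Chest radiograph unremarkable and oxygen weaned off.
neutral,irrelevant,negation,No active bleeding observed and absence of hemorrhage confirmed.
neutral,irrelevant,negation,No sign of bleeding during the stay and no hemorrhage reported.
neutral,irrelevant,negation,Absence of any bleeding event was documented at discharge.
fr,active_mb,plain,Hemorragie massive avec choc hemodynamique necessitant transfusion urgente.
fr,active_mb,plain,Saignement massif aigu avec anemie severe et etat de choc.
fr,active_mb,plain,Hemorragie intracranienne majeure confirmee par imagerie.
fr,active_mb,plain,Hemorragie profuse ayant necessite plusieurs culots en urgence.
fr,active_crnmb,plain,Epistaxis mineure resolue spontanement sans intervention.
fr,active_crnmb,plain,Rectorragie legere avec suintement minime a l examen.
fr,active_crnmb,plain,Hematurie limitee surveillee sans transfusion.
fr,active_crnmb,plain,Melena modere regle par mesures conservatrices.
fr,antecedent,plain,Antecedent d hemorragie documente deux ans avant l admission.
fr,antecedent,plain,Ancien saignement digestif rapporte bien avant ce sejour.
fr,antecedent,plain,Episode hemorragique ancien note dans le dossier medical.
fr,irrelevant,plain,Suivi cardiologique de routine avec signes vitaux stables.
fr,irrelevant,plain,Traitement revu et regime bien tolere pendant la nuit.
fr,irrelevant,plain,Physiotherapie poursuivie avec bonne mobilisation.
fr,irrelevant,plain,Fonction renale stable pendant le sejour.
fr,irrelevant,negation,Pas de saignement actif et absence d hemorragie confirmee.
fr,irrelevant,negation,Aucun signe de saignement durant le sejour.
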