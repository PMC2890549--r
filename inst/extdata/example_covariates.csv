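subject_id,age,sex,ethnicity,location,stage,family_history
S001,57,Male,Caucasian,Colon,II,Unknown
S002,67,Female,Caucasian,Colon,II,Yes
S003,53,Male,Caucasian,Rectum,IV,No
S004,54,Male,Caucasian,Colon,I,Yes
S005,63,Male,Caucasian,Rectum,III,Yes
S006,58,Female,Caucasian,Rectum,II,No
S007,66,Female,Caucasian,Colon,IV,No
S008,59,Male,Caucasian,Colon,IV,No
S009,73,Male,African American,Colon,IV,No
S010,60,Male,Caucasian,Rectum,II,No
S011,70,Female,Caucasian,Rectum,II,No
S012,50,Female,Caucasian,Rectum,III,Yes
S013,75,Female,Asian,Rectum,IV,Yes
S014,41,Male,African American,Colon,IV,No
S015,76,Female,Caucasian,Colon,IV,Yes
S016,35,Female,Caucasian,Colon,II,Yes
S017,67,Male,Caucasian,Colon,IV,No
S018,51,Male,Hispanic,Colon,II,No
S019,39,Female,Caucasian,Colon,III,No
S020,72,Male,African American,Colon,II,No
S021,66,Male,Caucasian,Colon,III,No
S022,76,Male,Caucasian,Rectum,III,Yes
S023,67,Male,Caucasian,Colon,III,No
S024,63,Male,Caucasian,Colon,III,Yes
S025,68,Male,Caucasian,Colon,IV,Yes
S026,47,Male,African American,Colon,I,No
S027,52,Male,Caucasian,Rectum,I,Yes
S028,71,Male,Hispanic,Rectum,III,No
S029,72,Female,Caucasian,Colon,II,Unknown
S030,45,Male,Caucasian,Rectum,II,No
S031,50,Female,Caucasian,Colon,III,No
S032,46,Female,Caucasian,Colon,III,No
S033,45,Male,African American,Colon,II,Unknown
S034,36,Female,African American,Colon,III,No
S035,53,Male,Caucasian,Rectum,I,No
S036,40,Female,Caucasian,Colon,II,No
S037,50,Male,Caucasian,Colon,III,No
S038,54,Female,Hispanic,Colon,II,Yes
S039,58,Male,African American,Colon,III,Yes
S040,75,Female,Caucasian,Rectum,II,No
S041,49,Female,Caucasian,Colon,II,Yes
S042,81,Male,Caucasian,Rectum,IV,No
S043,83,Male,Caucasian,Rectum,I,No
S044,57,Male,African American,Colon,IV,Yes
S045,65,Female,Caucasian,Rectum,III,No
S046,51,Female,Caucasian,Rectum,III,Yes
S047,65,Female,Caucasian,Rectum,III,No
S048,73,Female,Caucasian,Rectum,II,No
S049,55,Male,Caucasian,Colon,III,No
S050,53,Female,Caucasian,Colon,III,No
S051,83,Male,Caucasian,Colon,II,No
S052,53,Female,Caucasian,Rectum,III,No
S053,70,Male,Caucasian,Colon,III,No
S054,69,Female,Caucasian,Rectum,IV,No
S055,63,Female,Caucasian,Colon,IV,No
S056,48,Female,Caucasian,Colon,II,Yes
S057,43,Male,Caucasian,Rectum,II,Yes
S058,71,Female,Caucasian,Colon,I,No
S059,40,Male,Asian,Colon,IV,Yes
S060,62,Male,Caucasian,Rectum,III,No
S061,61,Male,Caucasian,Colon,II,Unknown
S062,46,Female,Caucasian,Rectum,III,No
S063,45,Female,Caucasian,Colon,IV,Yes
S064,61,Male,Caucasian,Rectum,II,No
S065,43,Female,African American,Colon,III,No
S066,83,Male,Caucasian,Both,IV,No
S067,60,Female,Caucasian,Colon,III,Yes
S068,46,Male,Caucasian,Rectum,IV,No
S069,47,Male,Caucasian,Colon,IV,No
S070,41,Female,Caucasian,Colon,IV,No
S071,76,Male,Caucasian,Rectum,IV,Yes
S072,39,Male,African American,Rectum,IV,No
S073,39,Male,Caucasian,Colon,IV,No
S074,66,Female,Caucasian,Colon,IV,No
S075,50,Male,Caucasian,Colon,III,Yes
S076,81,Female,Caucasian,Colon,II,No
S077,57,Male,African American,Colon,III,No
S078,71,Male,Caucasian,Colon,III,No
S079,53,Female,Caucasian,Colon,III,No
S080,44,Female,Caucasian,Colon,III,No
S081,73,Male,Caucasian,Colon,III,Yes
S082,56,Female,Caucasian,Rectum,II,Yes
S083,37,Male,Caucasian,Colon,II,No
S084,78,Male,Caucasian,Rectum,IV,No
S085,42,Female,Caucasian,Colon,I,No
S086,55,Male,Caucasian,Colon,III,Yes
S087,79,Female,Caucasian,Colon,IV,No
S088,36,Male,Caucasian,Colon,I,Yes
S089,45,Female,Caucasian,Colon,IV,No
S090,37,Female,Caucasian,Colon,III,Unknown
S091,38,Female,Caucasian,Colon,III,No
S092,49,Female,Caucasian,Colon,II,No
S093,64,Female,Caucasian,Rectum,IV,Yes
S094,76,Female,Caucasian,Colon,III,Yes
S095,69,Male,Caucasian,Colon,II,No
S096,56,Female,African American,Colon,III,Yes
S097,61,Female,Caucasian,Rectum,I,No
S098,54,Female,Caucasian,Colon,III,No
S099,46,Male,Caucasian,Rectum,IV,No
S100,40,Male,Caucasian,Rectum,I,No
S101,43,Male,Caucasian,Rectum,III,Unknown
S102,81,Female,Caucasian,Colon,II,No
S103,67,Male,Caucasian,Rectum,III,Yes
S104,37,Male,Caucasian,Rectum,III,No
S105,66,Female,Caucasian,Colon,III,Yes
S106,61,Male,Caucasian,Colon,III,No
S107,78,Male,Caucasian,Colon,II,Yes
S108,36,Female,Caucasian,Rectum,IV,No
S109,50,Male,Caucasian,Colon,IV,Unknown
S110,44,Female,African American,Colon,II,No
S111,76,Male,Asian,Colon,IV,No
S112,39,Female,African American,Colon,I,Unknown
S113,74,Female,Caucasian,Rectum,III,No
S114,67,Male,Caucasian,Colon,II,No
S115,51,Male,Caucasian,Colon,III,No
S116,83,Male,Caucasian,Colon,IV,No
S117,39,Male,Caucasian,Colon,III,Yes
S118,72,Female,Caucasian,Rectum,IV,No
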